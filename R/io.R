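## Plain-text serialization of the pipeline artifacts: delimited tables for
## the cohort and trajectory data, JSON for fitted models and results.

#' Write a raw cohort as delimited text
#'
#' Writes `observations.csv` (long format), `doses.csv`, `outcomes.csv`,
#' `events.csv` and, when present, `latents.csv` into `dir` (comma
#' separator, header row, UTF-8, '.' decimal).
#'
#' @param raw A `raw_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(raw, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("observations", "doses", "outcomes", "events", "latents")) {
    if (!is.null(raw[[tb]]))
      utils::write.csv(raw[[tb]], file.path(dir, paste0(tb, ".csv")),
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Read a raw cohort written by [write_cohort()]
#' @param dir Directory holding the cohort tables.
#' @return A `raw_cohort` (without config/truth metadata).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, paste0(f, ".csv"))
    if (file.exists(p)) utils::read.csv(p, fileEncoding = "UTF-8") else NULL
  }
  structure(list(observations = rd("observations"), doses = rd("doses"),
                 outcomes = rd("outcomes"), events = rd("events"),
                 latents = rd("latents")),
            class = "raw_cohort")
}

#' Write a trajectory table as one wide delimited file
#' @param traj A `trajectory_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trajectory table written by [write_trajectories()]
#' @param path File path.
#' @param feature_names Feature columns; inferred from the header when
#'   `NULL`.
#' @return A `trajectory_table`.
#' @export
read_trajectories <- function(path, feature_names = NULL) {
  out <- utils::read.csv(path, fileEncoding = "UTF-8", check.names = FALSE)
  class(out) <- c("trajectory_table", "data.frame")
  attr(out, "feature_names") <- feature_names %||%
    setdiff(names(out), c("patient_id", "bin_index", "vaso_dose",
                          "fluid_volume", "died_90d", "split"))
  out
}

#' Serialize a fitted state model and action grid to JSON
#'
#' @param model A `state_model`.
#' @param grid An `action_grid` (optional).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_state_model <- function(model, path, grid = NULL) {
  doc <- list(k = model$k, seed = model$seed, spec_name = model$spec$name,
              features = model$features,
              center = as.list(model$center), scale = as.list(model$scale),
              rotation = model$rotation, centroids = model$centroids,
              survived_id = model$survived_id, dead_id = model$dead_id)
  if (!is.null(grid))
    doc$action_grid <- list(vaso_edges = grid$vaso_edges,
                            fluid_edges = grid$fluid_edges)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a state model (and action grid) written by [write_state_model()]
#' @param path `.json` path.
#' @return List with `model` (`state_model`) and `grid` (`action_grid` or
#'   `NULL`).
#' @export
read_state_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(
    k = as.integer(doc$k), spec = feature_set_spec("CUSTOM",
                                                   features = doc$features),
    features = doc$features,
    center = unlist(doc$center), scale = unlist(doc$scale),
    rotation = if (length(doc$rotation)) as.matrix(doc$rotation),
    centroids = as.matrix(doc$centroids),
    seed = as.integer(doc$seed),
    survived_id = as.integer(doc$survived_id),
    dead_id = as.integer(doc$dead_id)), class = "state_model")
  grid <- NULL
  if (!is.null(doc$action_grid))
    grid <- structure(list(vaso_edges = unlist(doc$action_grid$vaso_edges),
                           fluid_edges = unlist(doc$action_grid$fluid_edges)),
                      class = "action_grid")
  list(model = model, grid = grid)
}

#' Write an MDP as sparse triplets plus a JSON header
#'
#' The transition model is stored as delimited triplet rows
#' `(s, a, s2, count, prob)` beside a JSON header with `k`, `gamma`, the
#' filter threshold and the initial-state distribution.
#'
#' @param mdp A `sepsis_mdp`.
#' @param prefix Output path prefix; writes `<prefix>.json` and
#'   `<prefix>_transitions.csv`.
#' @return `prefix`, invisibly.
#' @export
write_mdp <- function(mdp, prefix) {
  jsonlite::write_json(list(k = mdp$k, gamma = mdp$gamma,
                            threshold = mdp$threshold, d0 = mdp$d0),
                       paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE)
  utils::write.csv(mdp$trans, paste0(prefix, "_transitions.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' Read an MDP written by [write_mdp()]
#' @param prefix Path prefix used at write time.
#' @return A `sepsis_mdp` (raw counts are not round-tripped).
#' @export
read_mdp <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  trans <- utils::read.csv(paste0(prefix, "_transitions.csv"))
  thr <- suppressWarnings(as.integer(hdr$threshold))
  if (!length(thr)) thr <- NA_integer_
  new_mdp(as.integer(hdr$k), hdr$gamma, thr, trans,
          counts_raw = trans[0, c("s", "a", "s2", "n")],
          d0 = as.numeric(hdr$d0))
}

#' Serialize a policy to JSON
#' @param policy A `sepsis_policy`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_policy <- function(policy, path) {
  jsonlite::write_json(list(kind = policy$kind, action = policy$action,
                            prob = policy$prob,
                            n_states = policy$n_states,
                            n_actions = policy$n_actions),
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a policy written by [write_policy()]
#' @param path `.json` path.
#' @return A `sepsis_policy`.
#' @export
read_policy <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$kind, "deterministic")) {
    act <- as.integer(doc$action)
    new_policy(action = act, n_states = as.integer(doc$n_states),
               n_actions = as.integer(doc$n_actions))
  } else {
    new_policy(prob = as.matrix(doc$prob),
               n_states = as.integer(doc$n_states),
               n_actions = as.integer(doc$n_actions))
  }
}

#' Write a WIS evaluation result
#'
#' Writes `<prefix>.json` (estimate, mean value, lower bounds, B, seed) and
#' `<prefix>_bootstrap.csv` (the full bootstrap sample, one column, for
#' plotting).
#'
#' @param x A `wis_result` from [bootstrap_wis()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_wis_result <- function(x, prefix) {
  jsonlite::write_json(list(estimate = x$estimate,
                            mean_value = x$mean_value,
                            lb95 = x$lb95, lb99 = x$lb99, B = x$B,
                            seed = x$seed, n = x$n),
                       paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE)
  utils::write.csv(data.frame(wis = x$bootstrap),
                   paste0(prefix, "_bootstrap.csv"), row.names = FALSE)
  invisible(prefix)
}
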