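#' Specify a state-representation feature set
#'
#' Six stock representations are available: `FULL` (all 48 features),
#' `NO_LAB` (the 22 features available without laboratory latency), `CARDIO`
#' (six cardiorespiratory features), `BASELINE` (six low-information
#' reference features), `PCA80` (first 25 principal components, targeting 80%
#' of variance) and `PCA15` (first 2 components, about 15% of variance).
#' A custom explicit feature list or component count may also be given.
#'
#' @param name One of `"FULL"`, `"NO_LAB"`, `"CARDIO"`, `"BASELINE"`,
#'   `"PCA80"`, `"PCA15"`, or `"CUSTOM"`.
#' @param features Explicit feature list (a-priori sets).
#' @param n_components Number of principal components (PCA sets).
#' @return An object of class `feature_set_spec`.
#' @export
feature_set_spec <- function(name = c("FULL", "NO_LAB", "CARDIO", "BASELINE",
                                      "PCA80", "PCA15", "CUSTOM"),
                             features = NULL, n_components = NULL) {
  name <- match.arg(name)
  pca <- FALSE
  switch(name,
    FULL = { features <- features %||% default_feature_names() },
    NO_LAB = { features <- nolab_features() },
    CARDIO = { features <- cardio_features() },
    BASELINE = { features <- baseline_features() },
    PCA80 = { pca <- TRUE; n_components <- 25L },
    PCA15 = { pca <- TRUE; n_components <- 2L },
    CUSTOM = {
      pca <- !is.null(n_components)
      if (!pca && is.null(features))
        stop_config("CUSTOM spec needs features or n_components")
    })
  structure(list(name = name, pca = pca, features = features,
                 n_components = if (pca) as.integer(n_components)),
            class = "feature_set_spec")
}

## standardizer fitted on training rows only
fit_standardizer <- function(x_train) {
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

feature_matrix <- function(traj, features) {
  missing <- setdiff(features, names(traj))
  if (length(missing))
    stop_config("unknown feature(s): ", paste(missing, collapse = ", "))
  as.matrix(traj[, features, drop = FALSE])
}

#' Reduce a trajectory table to a state-representation feature set
#'
#' A-priori sets subset columns; PCA sets standardize with training-row
#' statistics, fit components on training rows only, and project every row.
#'
#' @param traj A `trajectory_table` (with a `split` column for PCA sets).
#' @param spec A [feature_set_spec()].
#' @return A `trajectory_table` whose feature columns are the representation
#'   (PC scores for PCA sets); the fitted transform (center, scale, rotation,
#'   explained variance) is in `attr(, "transform")`.
#' @export
select_features <- function(traj, spec) {
  stopifnot(inherits(spec, "feature_set_spec"))
  meta <- c("patient_id", "bin_index", "vaso_dose", "fluid_volume",
            "died_90d", "split")
  meta <- intersect(meta, names(traj))
  if (!spec$pca) {
    missing <- setdiff(spec$features, names(traj))
    if (length(missing))
      stop_config("unknown feature(s): ", paste(missing, collapse = ", "))
    out <- traj[, c(meta[1:2], spec$features, setdiff(meta, meta[1:2])),
                drop = FALSE]
    class(out) <- c("trajectory_table", "data.frame")
    attr(out, "feature_names") <- spec$features
    attr(out, "transform") <- NULL
    return(out)
  }
  feats <- traj_features(traj)
  X <- feature_matrix(traj, feats)
  train <- if (!is.null(traj$split)) traj$split == "train"
           else rep(TRUE, nrow(traj))
  std <- fit_standardizer(X[train, , drop = FALSE])
  Z <- sweep(sweep(X, 2L, std$center), 2L, std$scale, `/`)
  pc <- stats::prcomp(Z[train, , drop = FALSE], center = FALSE,
                      scale. = FALSE)
  m <- min(spec$n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(m), drop = FALSE]
  scores <- Z %*% rot
  colnames(scores) <- paste0("PC", seq_len(m))
  out <- cbind(traj[, meta[1:2], drop = FALSE],
               as.data.frame(scores),
               traj[, setdiff(meta, meta[1:2]), drop = FALSE])
  class(out) <- c("trajectory_table", "data.frame")
  attr(out, "feature_names") <- colnames(scores)
  ev <- pc$sdev^2
  attr(out, "transform") <- list(center = std$center, scale = std$scale,
                                 rotation = rot,
                                 explained_variance = cumsum(ev) / sum(ev))
  out
}

## k-means++ seeding: first centre uniform, then proportional to squared
## distance from the nearest chosen centre
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  if (k > 1L) for (j in 2:k) {
    tot <- sum(d2)
    i <- if (tot <= 0) sample.int(n, 1L)
         else sample.int(n, 1L, prob = d2 / tot)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' Fit the discrete state model
#'
#' Standardizes training-split rows (zero mean, unit variance per feature),
#' optionally projects onto principal components, seeds `k` centres by
#' k-means++ and runs Lloyd iterations to convergence. States `0..k-1` are
#' the clinical clusters; two absorbing states — survival (`k`) and death
#' (`k+1`) — complete the state space.
#'
#' @param traj A split `trajectory_table`.
#' @param spec A [feature_set_spec()].
#' @param k Number of clinical states (750 in the reference configuration,
#'   250 for retrained low-dimensional models).
#' @param seed Clustering seed (k-means++ is the only stochastic element).
#' @param max_iter Maximum Lloyd iterations.
#' @return An object of class `state_model` with the fitted standardizer,
#'   optional rotation, `k x d` centroid matrix, and absorbing state ids
#'   `survived_id = k`, `dead_id = k + 1`.
#' @export
fit_state_model <- function(traj, spec, k, seed = 1L, max_iter = 300L) {
  stopifnot(inherits(spec, "feature_set_spec"))
  red <- select_features(traj, spec)
  feats <- traj_features(red)
  train <- if (!is.null(red$split)) red$split == "train"
           else rep(TRUE, nrow(red))
  X <- feature_matrix(red, feats)[train, , drop = FALSE]
  if (nrow(X) < k)
    stop("fewer training rows (", nrow(X), ") than clusters (", k, ")",
         call. = FALSE)
  tf <- attr(red, "transform")
  if (is.null(tf)) {
    std <- fit_standardizer(X)
    Z <- sweep(sweep(X, 2L, std$center), 2L, std$scale, `/`)
  } else {
    std <- NULL                      # PCA path standardizes internally
    Z <- X
  }
  fit <- with_seed(seed, {
    init <- kmeanspp_init(Z, k)
    suppressWarnings(stats::kmeans(Z, centers = init, iter.max = max_iter,
                                   algorithm = "Lloyd"))
  })
  structure(list(k = as.integer(k), spec = spec, features = feats,
                 center = if (is.null(tf)) std$center else tf$center,
                 scale = if (is.null(tf)) std$scale else tf$scale,
                 rotation = tf$rotation,
                 explained_variance = tf$explained_variance,
                 centroids = unname(fit$centers), seed = as.integer(seed),
                 survived_id = as.integer(k), dead_id = as.integer(k + 1L)),
            class = "state_model")
}

## rows of `traj` -> clustering space of `model`
transform_rows <- function(traj, model) {
  if (is.null(model$rotation)) {
    X <- feature_matrix(traj, model$features)
    sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  } else {
    X <- feature_matrix(traj, names(model$center))
    Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
    Z %*% model$rotation
  }
}

#' Assign clinical states by nearest centroid
#'
#' Euclidean nearest-centroid assignment in the model's clustering space;
#' ties break toward the lowest centroid index.
#'
#' @param traj A `trajectory_table`.
#' @param model A fitted [fit_state_model()] object.
#' @return Integer vector of state ids in `[0, k)`, one per row of `traj`.
#' @export
assign_states <- function(traj, model) {
  Z <- transform_rows(traj, model)
  C <- model$centroids
  if (ncol(Z) != ncol(C))
    stop_config("feature dimensionality does not match the state model")
  ## argmin ||z - c||^2 = argmax z.c - ||c||^2 / 2
  S <- Z %*% t(C) - matrix(rowSums(C^2) / 2, nrow(Z), nrow(C), byrow = TRUE)
  max.col(S, ties.method = "first") - 1L
}

#' Fit the 25-level treatment action grid
#'
#' Each treatment (vasopressor rate, IV-fluid volume) is discretized into 5
#' bins: bin 0 is reserved for zero dose; the edges of bins 1..4 are the
#' 25th, 50th and 75th percentiles of the *nonzero* training doses (linear
#' interpolation). A dose equal to an edge falls in the lower bin
#' (right-closed intervals). The composite action id is
#' `5 * vaso_bin + fluid_bin`, giving 25 actions.
#'
#' @param vaso,fluid Training doses (vasopressor in ug/kg/min, fluid in
#'   mL/4h).
#' @return An object of class `action_grid` with `vaso_edges` and
#'   `fluid_edges`.
#' @export
fit_action_grid <- function(vaso, fluid) {
  edges <- function(x, what) {
    x <- x[!is.na(x) & x > 0]
    if (!length(x)) stop("all ", what, " doses are zero", call. = FALSE)
    unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  }
  structure(list(vaso_edges = edges(vaso, "vasopressor"),
                 fluid_edges = edges(fluid, "fluid")),
            class = "action_grid")
}

#' Map a dose to its grid bin
#' @param x Nonnegative dose values.
#' @param edges Nondecreasing quartile edges (length 3).
#' @return Integer bins in `0..4` (0 = zero dose).
#' @export
dose_to_bin <- function(x, edges) {
  stopifnot(all(x >= 0, na.rm = TRUE))
  dose_bin_known(x, edges)
}

#' Composite action id from treatment bins
#' @param vaso_bin,fluid_bin Integer bins in `0..4`.
#' @return Integer action ids in `[0, 25)`.
#' @export
action_id <- function(vaso_bin, fluid_bin) {
  stopifnot(all(vaso_bin %in% 0:4), all(fluid_bin %in% 0:4))
  as.integer(5L * vaso_bin + fluid_bin)
}

#' Assign composite actions to trajectory rows
#' @param traj A `trajectory_table`.
#' @param grid An [fit_action_grid()] object.
#' @return Integer action ids in `[0, 25)`, one per row.
#' @export
assign_actions <- function(traj, grid) {
  action_id(dose_to_bin(traj$vaso_dose, grid$vaso_edges),
            dose_to_bin(traj$fluid_volume, grid$fluid_edges))
}

#' Build per-patient state/action sequences
#'
#' Orders each patient's bins, assigns clinical states and actions, and
#' appends the absorbing state implied by the 90-day outcome (survival `k`,
#' death `k+1`), with the terminal reward granted on entry (+100 / -100).
#'
#' @param traj A `trajectory_table`.
#' @param model A fitted `state_model`.
#' @param grid A fitted `action_grid`.
#' @param split Optional split label (`"train"`/`"test"`) to restrict to.
#' @return List of trajectories, each `list(patient_id, states, actions,
#'   reward)` where `states` has length `T + 1` (terminal id last) and
#'   `actions` length `T`.
#' @export
build_sequences <- function(traj, model, grid, split = NULL) {
  if (!is.null(split) && !is.null(traj$split))
    traj <- traj[traj$split == split, , drop = FALSE]
  traj <- traj[order(traj$patient_id, traj$bin_index), , drop = FALSE]
  st <- assign_states(traj, model)
  ac <- assign_actions(traj, grid)
  idx <- split(seq_len(nrow(traj)), traj$patient_id)
  lapply(idx, function(i) {
    died <- traj$died_90d[i[1L]]
    term <- if (isTRUE(died) || died == 1) model$dead_id else model$survived_id
    list(patient_id = traj$patient_id[i[1L]],
         states = c(st[i], term),
         actions = ac[i],
         reward = if (term == model$dead_id) -100 else 100)
  })
}
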