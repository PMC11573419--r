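#' Experiment configuration for the model-comparison protocol
#'
#' @param models Character vector of model names from: `FULL`, `NO_LAB`,
#'   `CARDIO`, `BASELINE`, `PCA80`, `PCA15`, `RAND`, `NO_DRUGS`,
#'   `NO_VASOPRESSORS`, `NO_FLUID`, `CLINICIAN`.
#' @param k_values Cluster counts to train at (reference protocol: 750 and
#'   250).
#' @param n_trials Repeated re-clustering trials per model and k (reference
#'   protocol: 250).
#' @param gamma Discount factor.
#' @param B Bootstrap resamples per evaluation.
#' @param threshold Rare-transition filter threshold.
#' @param p_greedy Softening mass of greedy target policies under WIS.
#' @param master_seed Seed from which every trial seed is derived.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(models = c("FULL", "NO_LAB", "CARDIO",
                                         "BASELINE", "PCA80", "PCA15"),
                              k_values = c(750L, 250L),
                              n_trials = 250L,
                              gamma = 0.99, B = 2000L, threshold = 5L,
                              p_greedy = 0.99, master_seed = 1L) {
  known <- c("FULL", "NO_LAB", "CARDIO", "BASELINE", "PCA80", "PCA15",
             "RAND", "NO_DRUGS", "NO_VASOPRESSORS", "NO_FLUID", "CLINICIAN")
  if (!length(models) || !all(models %in% known))
    stop_config("unknown model name(s): ",
                paste(setdiff(models, known), collapse = ", "))
  stopifnot(n_trials >= 1L, length(k_values) >= 1L)
  structure(list(models = models, k_values = as.integer(k_values),
                 n_trials = as.integer(n_trials), gamma = gamma,
                 B = as.integer(B), threshold = as.integer(threshold),
                 p_greedy = p_greedy, master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

model_spec <- function(model) {
  switch(model,
         FULL = feature_set_spec("FULL"),
         NO_LAB = feature_set_spec("NO_LAB"),
         CARDIO = feature_set_spec("CARDIO"),
         BASELINE = feature_set_spec("BASELINE"),
         PCA80 = feature_set_spec("PCA80"),
         PCA15 = feature_set_spec("PCA15"),
         feature_set_spec("FULL"))  # constrained / clinician models
}

#' Run one model trial: cluster, fit the MDP, solve, evaluate off-policy
#'
#' One full pass of the pipeline on an already preprocessed, split
#' trajectory table: feature selection, k-means++ state model (under
#' `seed`), action grid and MDP on the training split, policy iteration (or
#' the requested constrained/reference policy), and bootstrapped WIS of the
#' target and clinician policies on the held-out test split. Trial-to-trial
#' variation comes from the clustering seed only.
#'
#' The behaviour policy used in the importance ratios is estimated from the
#' evaluation split's own logged transitions, which guarantees positive
#' probability on every logged action. Clinical states the optimizer leaves
#' undefined (no available action after filtering) fall back to the
#' clinician-majority action of the evaluation split.
#'
#' @param traj Preprocessed `trajectory_table` with a `split` column.
#' @param model Model name (see [experiment_config()]).
#' @param k Number of clinical states.
#' @param seed Clustering seed of this trial.
#' @param gamma,threshold,B,p_greedy,delta Pipeline parameters.
#' @param boot_seed Seed of the bootstrap resampling (defaults to
#'   `seed + 1`).
#' @param clin_boot_seed Seed of the clinician-policy bootstrap; keep fixed
#'   across trials that share a split so the clinician row is invariant to
#'   re-clustering.
#' @return List with `summary` (one-row data.frame: model, k, seed,
#'   estimate, mean_policy_value, lb95, lb99, clinician_value,
#'   clinician_lb95), and components `state_model`, `action_grid`, `mdp`,
#'   `policy`, `wis`, `clinician_wis`, `visit_weights`.
#' @export
run_trial <- function(traj, model, k, seed, gamma = 0.99, threshold = 5L,
                      B = 2000L, p_greedy = 0.99, delta = 0.01,
                      boot_seed = NULL, clin_boot_seed = 1L) {
  spec <- model_spec(model)
  sm <- fit_state_model(traj, spec, k = k, seed = seed)
  train <- traj[traj$split == "train", , drop = FALSE]
  grid <- fit_action_grid(train$vaso_dose, train$fluid_volume)
  seq_train <- build_sequences(traj, sm, grid, split = "train")
  seq_test <- build_sequences(traj, sm, grid, split = "test")
  mdp <- build_mdp(seq_train, k = k, gamma = gamma, threshold = threshold)

  ## behaviour policy on the evaluation split (positive on logged actions)
  ct_test <- count_transitions(seq_test, n_states = mdp$n_states)
  pi_c <- estimate_clinician_policy(ct_test$counts, n_states = mdp$n_states,
                                    delta = delta,
                                    available = mdp$available)

  ## clinician-majority fallback for states the optimizer leaves undefined
  majority <- function() {
    M <- matrix(0, mdp$n_states, mdp$n_actions)
    sa <- rowsum(ct_test$counts$n, ct_test$counts$s * 25L + ct_test$counts$a)
    kk <- as.integer(rownames(sa))
    M[cbind(kk %/% 25L + 1L, kk %% 25L + 1L)] <- sa[, 1L]
    max.col(M, ties.method = "first") - 1L
  }

  pi_target <- NULL
  solved <- NULL
  if (model %in% c("FULL", "NO_LAB", "CARDIO", "BASELINE", "PCA80",
                   "PCA15")) {
    solved <- policy_iteration(mdp)
    act <- solved$policy$action
    und <- is.na(act)
    if (any(und)) act[und] <- majority()[und]
    avail <- mdp$available
    avail[cbind(which(und), act[und] + 1L)] <- TRUE
    pi_target <- soften_policy(new_policy(action = act,
                                          n_states = mdp$n_states),
                               avail, p_greedy)
  } else if (model == "RAND") {
    P <- mdp$available / pmax(rowSums(mdp$available), 1)
    pi_target <- new_policy(prob = P, n_states = mdp$n_states)
  } else if (model == "NO_DRUGS") {
    pi_target <- soften_policy(new_policy(action = rep(0L, mdp$n_states),
                                          n_states = mdp$n_states),
                               mdp$available, p_greedy)
  } else if (model %in% c("NO_VASOPRESSORS", "NO_FLUID")) {
    allowed <- if (model == "NO_VASOPRESSORS") 0:4 else seq(0L, 20L, 5L)
    sub <- restrict_mdp(mdp, allowed)
    act <- policy_iteration(sub)$policy$action
    act[is.na(act)] <- 0L
    avail <- sub$available
    avail[cbind(seq_len(mdp$n_states), act + 1L)] <- TRUE
    pi_target <- soften_policy(new_policy(action = act,
                                          n_states = mdp$n_states),
                               avail, p_greedy)
  } else if (model == "CLINICIAN") {
    pi_target <- pi_c
  }

  clin <- bootstrap_wis(seq_test, pi_c, pi_c, gamma, B = B,
                        seed = clin_boot_seed)
  wis <- if (model == "CLINICIAN") clin else
    bootstrap_wis(seq_test, pi_target, pi_c, gamma, B = B,
                  seed = boot_seed %||% (seed + 1L))

  visits <- tabulate(unlist(lapply(seq_test, function(x)
    utils::head(x$states, -1L))) + 1L, nbins = mdp$n_states)

  list(summary = data.frame(model = model, k = k, seed = seed,
                            estimate = wis$estimate,
                            mean_policy_value = wis$mean_value,
                            lb95 = wis$lb95, lb99 = wis$lb99,
                            clinician_value = clin$estimate,
                            clinician_lb95 = clin$lb95,
                            stringsAsFactors = FALSE),
       state_model = sm, action_grid = grid, mdp = mdp,
       policy = pi_target, solved = solved, pi_c = pi_c,
       wis = wis, clinician_wis = clin, visit_weights = visits)
}

#' Run the full model-comparison protocol
#'
#' Executes every `(model, k)` combination for `n_trials` re-clustering
#' trials with seeds derived from the master seed, and summarizes each
#' model's best mean policy value and best 95%/99% lower bounds over its
#' trials.
#'
#' @param traj Preprocessed, split `trajectory_table`.
#' @param config An [experiment_config()].
#' @return List with `trials` (one row per trial) and `best` (per model and
#'   k: top mean value and top lower bounds).
#' @export
run_comparison <- function(traj, config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  for (mi in seq_along(config$models)) {
    model <- config$models[mi]
    for (ki in seq_along(config$k_values)) {
      k <- config$k_values[ki]
      for (trial in seq_len(config$n_trials)) {
        seed <- derive_seed(config$master_seed, mi, ki, trial)
        res <- run_trial(traj, model, k, seed, gamma = config$gamma,
                         threshold = config$threshold, B = config$B,
                         p_greedy = config$p_greedy,
                         boot_seed = derive_seed(config$master_seed, mi, ki,
                                                 trial, 2L),
                         clin_boot_seed = config$master_seed)
        s <- res$summary
        s$trial <- trial
        rows[[length(rows) + 1L]] <- s
      }
    }
  }
  trials <- do.call(rbind, rows)
  key <- interaction(trials$model, trials$k, drop = TRUE)
  best <- do.call(rbind, lapply(split(trials, key), function(d)
    data.frame(model = d$model[1L], k = d$k[1L],
               best_mean_value = max(d$mean_policy_value),
               best_lb95 = max(d$lb95), best_lb99 = max(d$lb99),
               clinician_value = d$clinician_value[1L],
               stringsAsFactors = FALSE)))
  rownames(best) <- NULL
  list(trials = trials, best = best)
}

#' Action-frequency matrix of a policy
#'
#' Frequency of each (vasopressor bin, IV-fluid bin) combination under the
#' policy, averaged over states weighted by their empirical visit counts in
#' the evaluation split.
#'
#' @param policy A `sepsis_policy` (or probability matrix).
#' @param visit_weights Nonnegative per-state visit counts (length
#'   `n_states`; absorbing states are ignored via zero weights).
#' @return A `5 x 5` matrix (rows: vasopressor bins 0..4, columns: fluid
#'   bins 0..4) summing to 1.
#' @export
action_frequency_table <- function(policy, visit_weights) {
  P <- if (inherits(policy, "sepsis_policy")) policy_matrix(policy)
       else policy
  stopifnot(length(visit_weights) == nrow(P))
  w <- visit_weights / sum(visit_weights)
  freq <- colSums(P * w)
  freq <- freq / sum(freq)
  matrix(freq, 5L, 5L, byrow = TRUE,
         dimnames = list(vaso_bin = 0:4, fluid_bin = 0:4))
}

#' Agreement between a learned policy and the latent ground truth
#'
#' For synthetic cohorts only: the fraction of state-visits at which the
#' policy's action equals the generator's latent-optimal action for the
#' visit's true severity level.
#'
#' @param policy A deterministic `sepsis_policy` (or action vector).
#' @param traj Preprocessed `trajectory_table` (bin indices aligned with the
#'   generator's recording clock).
#' @param model The fitted `state_model` used by the policy.
#' @param raw The generating `raw_cohort` (for `latents` and `truth`).
#' @param split Which split's visits to score (default `"train"`).
#' @return Fraction in `[0, 1]` of visits where the actions agree (visits in
#'   states with no defined action are counted as disagreement).
#' @export
policy_match_rate <- function(policy, traj, model, raw, split = "train") {
  act <- if (inherits(policy, "sepsis_policy")) policy$action else policy
  if (!is.null(split) && !is.null(traj$split))
    traj <- traj[traj$split == split, , drop = FALSE]
  st <- assign_states(traj, model)
  key <- paste(traj$patient_id, traj$bin_index)
  lat <- raw$latents
  z <- lat$latent[match(key, paste(lat$patient_id, lat$bin_index))]
  ok <- !is.na(z)
  opt <- raw$truth$optimal_action_by_latent[z[ok]]
  chosen <- act[st[ok] + 1L]
  mean(!is.na(chosen) & chosen == opt)
}
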