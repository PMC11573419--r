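#' Soften a deterministic policy for importance sampling
#'
#' Weighted importance sampling needs the target policy to give positive
#' probability to logged actions; a strictly deterministic greedy policy
#' would zero out almost every trajectory. The greedy action keeps mass
#' `p_greedy` and the remainder is spread uniformly over the other available
#' actions of the state (a state with a single available action keeps mass
#' 1 on it).
#'
#' @param policy A deterministic `sepsis_policy`.
#' @param available Logical availability matrix `n_states x n_actions`.
#' @param p_greedy Probability mass of the greedy action (default 0.99).
#' @return A stochastic `sepsis_policy`.
#' @export
soften_policy <- function(policy, available, p_greedy = 0.99) {
  stopifnot(policy$kind == "deterministic", p_greedy > 0, p_greedy <= 1)
  P <- matrix(0, policy$n_states, policy$n_actions)
  for (s in which(!is.na(policy$action))) {
    g <- policy$action[s] + 1L
    others <- setdiff(which(available[s, ]), g)
    if (length(others)) {
      P[s, g] <- p_greedy
      P[s, others] <- (1 - p_greedy) / length(others)
    } else {
      P[s, g] <- 1
    }
  }
  new_policy(prob = P, n_states = policy$n_states,
             n_actions = policy$n_actions)
}

#' Cumulative importance ratios of one trajectory
#'
#' Running product of per-step likelihood ratios
#' `pi_AI(a_t | s_t) / pi_C(a_t | s_t)` along the logged steps.
#'
#' @param traj A logged trajectory (`list(states, actions, reward)`).
#' @param pi_ai,pi_c Target and behaviour policies (`sepsis_policy` or
#'   probability matrices).
#' @return Numeric vector `rho_{1:t}`, `t = 1..T`.
#' @export
importance_ratios <- function(traj, pi_ai, pi_c) {
  Pa <- if (inherits(pi_ai, "sepsis_policy")) policy_matrix(pi_ai) else pi_ai
  Pc <- if (inherits(pi_c, "sepsis_policy")) policy_matrix(pi_c) else pi_c
  T <- length(traj$actions)
  idx <- cbind(traj$states[seq_len(T)] + 1L, traj$actions + 1L)
  den <- Pc[idx]
  if (any(den <= 0))
    stop("behaviour policy gives zero probability to a logged action",
         call. = FALSE)
  cumprod(Pa[idx] / den)
}

## precompute the per-trajectory quantities WIS needs: the cumulative-ratio
## matrix (frozen at rho_{1:T} beyond each trajectory's horizon), horizons,
## and discounted returns
wis_prepare <- function(trajs, pi_ai, pi_c, gamma) {
  Pa <- if (inherits(pi_ai, "sepsis_policy")) policy_matrix(pi_ai) else pi_ai
  Pc <- if (inherits(pi_c, "sepsis_policy")) policy_matrix(pi_c) else pi_c
  N <- length(trajs)
  stopifnot(N >= 1L)
  horizon <- vapply(trajs, function(x) length(x$actions), integer(1))
  Tmax <- max(horizon)
  rho <- matrix(0, N, Tmax)
  G <- numeric(N)
  for (i in seq_len(N)) {
    x <- trajs[[i]]
    T <- horizon[i]
    idx <- cbind(x$states[seq_len(T)] + 1L, x$actions + 1L)
    den <- Pc[idx]
    if (any(den <= 0))
      stop("behaviour policy gives zero probability to a logged action",
           call. = FALSE)
    rr <- cumprod(Pa[idx] / den)
    rho[i, ] <- c(rr, rep(rr[T], Tmax - T))
    ## rewards are zero except on entering the absorbing state
    G[i] <- gamma^(T - 1L) * x$reward
  }
  list(rho = rho, horizon = horizon, G = G, N = N)
}

## WIS point estimate on a (re)sample of trajectory indices
wis_from_prep <- function(prep, idx = seq_len(prep$N)) {
  rho <- prep$rho[idx, , drop = FALSE]
  w <- colMeans(rho)
  own <- rho[cbind(seq_along(idx), prep$horizon[idx])]
  if (all(own == 0))
    stop("all importance weights are zero; no overlap between policies",
         call. = FALSE)
  v <- numeric(length(idx))
  pos <- own > 0
  v[pos] <- own[pos] / w[prep$horizon[idx][pos]] * prep$G[idx][pos]
  list(wis = mean(v), v_wis = v)
}

#' Weighted importance sampling estimate of a policy's value
#'
#' Per trajectory, `V_WIS = rho_{1:T} / w_T * sum_t gamma^(t-1) r_t`, where
#' `w_t` is the across-trajectory mean cumulative ratio at step `t` (ratios
#' are frozen at `rho_{1:T}` beyond a trajectory's own horizon so the running
#' mean is defined for variable-length stays); the estimator is the average
#' of the per-trajectory values.
#'
#' @param trajs List of logged trajectories (`list(states, actions,
#'   reward)`).
#' @param pi_ai Target policy (stochastic, e.g. [soften_policy()] output).
#' @param pi_c Behaviour (clinician) policy; must be positive on every
#'   logged action.
#' @param gamma Discount factor.
#' @return An object of class `wis_result` with elements `estimate` and
#'   `v_wis` (per-trajectory values).
#' @export
wis_estimate <- function(trajs, pi_ai, pi_c, gamma = 0.99) {
  prep <- wis_prepare(trajs, pi_ai, pi_c, gamma)
  est <- wis_from_prep(prep)
  structure(list(estimate = est$wis, v_wis = est$v_wis, n = prep$N),
            class = "wis_result")
}

#' Bootstrapped WIS with confidence lower bounds
#'
#' Resamples trajectories with replacement `B` times, recomputing the WIS
#' estimator (including the weight normalization `w_t`) within each
#' resample. The 95% and 99% lower bounds are the 5th and 1st percentiles of
#' the bootstrap distribution; its mean is reported as the mean policy
#' value.
#'
#' @inheritParams wis_estimate
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed Resampling seed.
#' @return A `wis_result` with `estimate` (full-sample WIS), `mean_value`
#'   (bootstrap mean), `lb95`, `lb99`, the full `bootstrap` vector, `B` and
#'   `seed`.
#' @export
bootstrap_wis <- function(trajs, pi_ai, pi_c, gamma = 0.99, B = 2000L,
                          seed = 1L) {
  stopifnot(length(trajs) >= 1L)
  prep <- wis_prepare(trajs, pi_ai, pi_c, gamma)
  point <- wis_from_prep(prep)
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(prep$N, prep$N, replace = TRUE)
      tryCatch(wis_from_prep(prep, idx)$wis, error = function(e) NA_real_)
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  structure(list(estimate = point$wis, v_wis = point$v_wis,
                 mean_value = mean(boot),
                 lb95 = unname(stats::quantile(boot, 0.05, type = 7)),
                 lb99 = unname(stats::quantile(boot, 0.01, type = 7)),
                 bootstrap = boot, B = as.integer(B),
                 seed = as.integer(seed), n = prep$N),
            class = "wis_result")
}

#' @export
print.wis_result <- function(x, ...) {
  cat(sprintf("WIS estimate %.4f (n = %d trajectories)\n", x$estimate, x$n))
  if (!is.null(x$mean_value))
    cat(sprintf("bootstrap mean %.4f, lb95 %.4f, lb99 %.4f (B = %d)\n",
                x$mean_value, x$lb95, x$lb99, x$B))
  invisible(x)
}

#' Build and evaluate the policy-constrained baselines
#'
#' Four fixed references: `RAND` acts uniformly over the available actions
#' of each state; `NO_DRUGS` always takes action 0 (no treatment);
#' `NO_VASOPRESSORS` forces the vasopressor bin to 0 and chooses the fluid
#' bin by policy iteration on the fluid-only restricted MDP; `NO_FLUID` is
#' symmetric. Each is evaluated with [bootstrap_wis()].
#'
#' @param mdp A fitted `sepsis_mdp`.
#' @param trajs Logged evaluation trajectories.
#' @param pi_c Behaviour policy on the evaluation trajectories.
#' @param gamma Discount factor.
#' @param B,seed Bootstrap parameters.
#' @param p_greedy Softening mass for the deterministic constrained
#'   policies.
#' @return Named list of `wis_result` objects with the constructed policies
#'   in `attr(, "policies")`.
#' @export
evaluate_constrained_policies <- function(mdp, trajs, pi_c, gamma = 0.99,
                                          B = 2000L, seed = 1L,
                                          p_greedy = 0.99) {
  ns <- mdp$n_states
  rand <- {
    P <- mdp$available / pmax(rowSums(mdp$available), 1)
    new_policy(prob = P, n_states = ns)
  }
  no_drugs <- soften_policy(
    new_policy(action = rep(0L, ns), n_states = ns),
    mdp$available, p_greedy)
  constrained_pi <- function(allowed, forced) {
    sub <- restrict_mdp(mdp, allowed)
    act <- policy_iteration(sub)$policy$action
    act[is.na(act)] <- forced
    soften_policy(new_policy(action = act, n_states = ns),
                  sub$available, p_greedy)
  }
  no_vaso <- constrained_pi(0:4, 0L)                 # vaso bin forced to 0
  no_fluid <- constrained_pi(seq(0L, 20L, by = 5L), 0L)  # fluid bin 0
  policies <- list(RAND = rand, NO_DRUGS = no_drugs,
                   NO_VASOPRESSORS = no_vaso, NO_FLUID = no_fluid)
  out <- lapply(policies, function(p)
    bootstrap_wis(trajs, p, pi_c, gamma, B = B, seed = seed))
  attr(out, "policies") <- policies
  out
}

#' Calibration of policy value against observed mortality
#'
#' Bins evaluated policy values into equal-width bins over `[-100, 100]` and
#' reports the empirical 90-day mortality of the trajectories in each bin;
#' empty bins are omitted.
#'
#' @param values Per-trajectory (or per-patient) evaluated policy values.
#' @param died Logical/0-1 vector of 90-day mortality, same length.
#' @param n_bins Number of equal-width value bins (default 10).
#' @return Data.frame (`value_mid`, `mortality`, `n`).
#' @export
calibration_curve <- function(values, died, n_bins = 10L) {
  stopifnot(length(values) == length(died))
  breaks <- seq(-100, 100, length.out = n_bins + 1L)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mort <- tapply(as.numeric(died), bin, mean)
  cnt <- tapply(died, bin, length)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  data.frame(value_mid = mids[as.integer(names(mort))],
             mortality = as.numeric(mort),
             n = as.integer(cnt))
}
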