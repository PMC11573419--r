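# Independent oracles and tiny fixture builders shared across tests.
# The oracles use dense arrays and plain loops on purpose: they must stay
# independent of the package's sparse-triplet code paths.

## Random tabular MDP with every action available and a guaranteed minimum
## probability of reaching an absorbing state, so trajectories terminate.
random_mdp <- function(k, n_actions = 3L, seed = 1L, gamma = 0.99,
                       p_absorb_min = 0.05) {
  set.seed(seed)
  rows <- list()
  for (s in 0:(k - 1L)) {
    for (a in 0:(n_actions - 1L)) {
      w <- stats::rexp(k + 2L)
      p <- w / sum(w)
      ab <- p[k + 1L] + p[k + 2L]
      if (ab < p_absorb_min) {
        p <- p * (1 - p_absorb_min) / (1 - ab)
        extra <- (p_absorb_min - ab) / 2
        p[k + 1L] <- p[k + 1L] + extra
        p[k + 2L] <- p[k + 2L] + extra
        p <- p / sum(p)
      }
      rows[[length(rows) + 1L]] <- data.frame(s = s, a = a,
                                              s2 = 0:(k + 1L), prob = p)
    }
  }
  d0 <- stats::rexp(k); d0 <- d0 / sum(d0)
  mdp_from_probabilities(do.call(rbind, rows), k = k, gamma = gamma,
                         d0 = c(d0, 0, 0), n_actions = n_actions)
}

## Dense transition array T[s, a, s2] (1-based) from an mdp object.
dense_T <- function(mdp) {
  arr <- array(0, c(mdp$n_states, mdp$n_actions, mdp$n_states))
  tr <- mdp$trans
  arr[cbind(tr$s + 1L, tr$a + 1L, tr$s2 + 1L)] <- tr$prob
  arr
}

## Long-horizon value iteration on dense arrays; independent of the
## package's policy-evaluation solver.
value_iteration_oracle <- function(mdp, n_iter = 3000L, return_q = FALSE) {
  arr <- dense_T(mdp)
  ns <- mdp$n_states; na <- mdp$n_actions
  R <- mdp$reward
  avail <- mdp$available
  v <- numeric(ns)
  Tm <- matrix(arr, ns * na, ns)  # (s, a) rows stacked column-major
  for (i in seq_len(n_iter)) {
    q <- Tm %*% (R + mdp$gamma * v)
    Q <- matrix(q, ns, na)
    Q[!avail] <- -Inf
    vnew <- pmax(apply(Q, 1L, max), -Inf)
    vnew[!is.finite(vnew)] <- 0
    vnew[c(mdp$survived_id, mdp$dead_id) + 1L] <- 0
    if (max(abs(vnew - v)) < 1e-13) { v <- vnew; break }
    v <- vnew
  }
  if (!return_q) return(v)
  Q <- matrix(Tm %*% (R + mdp$gamma * v), ns, na)
  Q[!avail] <- NA_real_
  list(v = v, q = Q)
}

## Exact evaluation of a deterministic or stochastic policy by long fixed-
## point iteration on dense arrays (oracle for policy_evaluation).
policy_value_oracle <- function(mdp, policy, n_iter = 3000L) {
  arr <- dense_T(mdp)
  ns <- mdp$n_states
  R <- mdp$reward
  P <- if (inherits(policy, "sepsis_policy")) policy_matrix(policy)
       else policy
  ## restrict to available actions, renormalize (matches the solver contract)
  P <- P * mdp$available
  rs <- rowSums(P)
  P[rs > 0, ] <- P[rs > 0, , drop = FALSE] / rs[rs > 0]
  v <- numeric(ns)
  for (i in seq_len(n_iter)) {
    ev <- sapply(seq_len(ns), function(s) {
      if (rs[s] == 0) return(0)
      sum(sapply(which(P[s, ] > 0), function(a)
        P[s, a] * sum(arr[s, a, ] * (R + mdp$gamma * v))))
    })
    ev[c(mdp$survived_id, mdp$dead_id) + 1L] <- 0
    if (max(abs(ev - v)) < 1e-13) { v <- ev; break }
    v <- ev
  }
  v
}

## Uniformly random deterministic policy over available actions.
random_policy <- function(mdp) {
  act <- rep(NA_integer_, mdp$n_states)
  for (s in seq_len(mdp$n_states)) {
    av <- which(mdp$available[s, ])
    if (length(av)) act[s] <- av[sample.int(length(av), 1L)] - 1L
  }
  new_policy(action = act, n_states = mdp$n_states,
             n_actions = mdp$n_actions)
}

## Straightforward loop-based WIS + percentile bootstrap, kept independent
## of the package's vectorized implementation (same resampling scheme).
wis_reference <- function(trajs, Pa, Pc, gamma, B = NULL, seed = NULL) {
  N <- length(trajs)
  Tv <- vapply(trajs, function(x) length(x$actions), integer(1))
  Tmax <- max(Tv)
  rho <- matrix(0, N, Tmax)
  G <- numeric(N)
  for (i in seq_len(N)) {
    x <- trajs[[i]]
    r <- 1
    for (t in seq_len(Tv[i])) {
      r <- r * Pa[x$states[t] + 1L, x$actions[t] + 1L] /
        Pc[x$states[t] + 1L, x$actions[t] + 1L]
      rho[i, t] <- r
    }
    if (Tv[i] < Tmax) rho[i, (Tv[i] + 1L):Tmax] <- rho[i, Tv[i]]
    G[i] <- gamma^(Tv[i] - 1L) * x$reward
  }
  point <- function(idx) {
    w <- colMeans(rho[idx, , drop = FALSE])
    v <- numeric(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      v[j] <- if (rho[i, Tv[i]] == 0) 0 else rho[i, Tv[i]] / w[Tv[i]] * G[i]
    }
    mean(v)
  }
  est <- point(seq_len(N))
  if (is.null(B)) return(est)
  set.seed(seed)
  boot <- numeric(B)
  for (b in seq_len(B)) boot[b] <- point(sample.int(N, N, replace = TRUE))
  list(estimate = est, boot = boot,
       lb95 = unname(quantile(boot, 0.05, type = 7)),
       lb99 = unname(quantile(boot, 0.01, type = 7)))
}

## Small preprocessed synthetic trajectory table shared by heavier tests;
## built once per test run.
small_pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_patients = 400, seed = 421,
                           treatment_effect = 2)
      raw <- generate_cohort(cfg)
      cache <<- list(raw = raw, traj = preprocess_cohort(raw))
    }
    cache
  }
})
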