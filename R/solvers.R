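#' Construct a policy
#'
#' @param action Integer vector of 0-based action ids per state (`NA` for
#'   states with no defined action) — deterministic policies.
#' @param prob Matrix `n_states x n_actions` of action probabilities —
#'   stochastic policies (rows with positive mass must sum to 1).
#' @param n_states,n_actions State/action space sizes.
#' @return An object of class `sepsis_policy` with `kind` `"deterministic"`
#'   or `"stochastic"`.
#' @export
new_policy <- function(action = NULL, prob = NULL, n_states,
                       n_actions = 25L) {
  if (is.null(action) == is.null(prob))
    stop_config("supply exactly one of action or prob")
  if (!is.null(prob)) {
    stopifnot(nrow(prob) == n_states, ncol(prob) == n_actions)
    rs <- rowSums(prob)
    if (any(rs > 0 & abs(rs - 1) > 1e-12))
      stop_config("stochastic policy rows must sum to 1")
    kind <- "stochastic"
  } else {
    stopifnot(length(action) == n_states)
    kind <- "deterministic"
  }
  structure(list(kind = kind, action = action, prob = prob,
                 n_states = as.integer(n_states),
                 n_actions = as.integer(n_actions)),
            class = "sepsis_policy")
}

#' Action-probability matrix of a policy
#' @param policy A `sepsis_policy`.
#' @return Matrix `n_states x n_actions`; deterministic policies become
#'   one-hot rows (all-zero for undefined states).
#' @export
policy_matrix <- function(policy) {
  if (policy$kind == "stochastic") return(policy$prob)
  P <- matrix(0, policy$n_states, policy$n_actions)
  def <- which(!is.na(policy$action))
  P[cbind(def, policy$action[def] + 1L)] <- 1
  P
}

## per-triplet policy weight pi(a | s), restricted to available actions and
## renormalized (stochastic policies may put mass on filtered pairs)
triplet_policy_weight <- function(mdp, policy) {
  tr <- mdp$trans
  if (policy$kind == "deterministic") {
    act <- policy$action[tr$s + 1L]
    as.numeric(!is.na(act) & act == tr$a)
  } else {
    P <- policy$prob * mdp$available
    rs <- rowSums(P)
    pos <- rs > 0
    P[pos, ] <- P[pos, , drop = FALSE] / rs[pos]
    P[cbind(tr$s + 1L, tr$a + 1L)]
  }
}

#' Evaluate a policy on the MDP (Bellman linear system)
#'
#' Solves `V(s) = sum_a pi(a|s) sum_s' T(s'|s,a) [R(s') + gamma V(s')]`
#' exactly by a sparse direct solve over the clinical states. Absorbing
#' states have value 0 (the terminal reward is collected on entry); states
#' with no available action under the policy fall back to value 0.
#'
#' @param mdp A `sepsis_mdp`.
#' @param policy A `sepsis_policy` defined on the states with available
#'   actions.
#' @return Numeric value vector of length `n_states` (indexed by
#'   `state id + 1`).
#' @export
policy_evaluation <- function(mdp, policy) {
  stopifnot(inherits(mdp, "sepsis_mdp"), inherits(policy, "sepsis_policy"))
  tr <- mdp$trans
  w <- triplet_policy_weight(mdp, policy) * tr$prob
  keep <- w > 0
  V <- numeric(mdp$n_states)
  if (!any(keep)) return(V)
  s1 <- tr$s[keep] + 1L
  s2 <- tr$s2[keep] + 1L
  wk <- w[keep]
  ## states with policy mass; all others have V = 0
  D <- sort(unique(s1))
  r <- rowsum(wk * mdp$reward[s2], s1)
  b <- r[match(D, as.integer(rownames(r))), 1L]
  clin <- s2 <= mdp$k & (s2 %in% D)
  i <- match(s1[clin], D)
  j <- match(s2[clin], D)
  P <- Matrix::sparseMatrix(i = i, j = j, x = wk[clin],
                            dims = c(length(D), length(D)))
  A <- Matrix::Diagonal(length(D)) - mdp$gamma * P
  V[D] <- as.numeric(Matrix::solve(A, b))
  V
}

#' State-action values from a state value function
#'
#' `Q(s, a) = sum_s' T(s'|s,a) [R(s') + gamma V(s')]` over available pairs;
#' unavailable pairs are `NA`.
#'
#' @param mdp A `sepsis_mdp`.
#' @param v Value vector of length `n_states`.
#' @return Matrix `n_states x n_actions`.
#' @export
q_from_v <- function(mdp, v) {
  stopifnot(length(v) == mdp$n_states)
  tr <- mdp$trans
  Q <- matrix(NA_real_, mdp$n_states, mdp$n_actions)
  if (!nrow(tr)) return(Q)
  s2 <- tr$s2 + 1L
  contrib <- tr$prob * (mdp$reward[s2] + mdp$gamma * v[s2])
  key <- tr$s * mdp$n_actions + tr$a
  qs <- rowsum(contrib, key)
  kk <- as.integer(rownames(qs))
  Q[cbind(kk %/% mdp$n_actions + 1L, kk %% mdp$n_actions + 1L)] <- qs[, 1L]
  Q
}

#' Solve the MDP by policy iteration
#'
#' Alternates exact policy evaluation with greedy improvement
#' (`pi(s) <- argmax_a Q(s, a)`) starting from the lowest-index available
#' action in each state, until the policy is unchanged. Ties break toward
#' the lowest action id; states with no available action are excluded.
#'
#' @param mdp A `sepsis_mdp`.
#' @param max_iter Safety bound on improvement steps (finite MDPs terminate
#'   far earlier).
#' @return List with `policy` (deterministic `sepsis_policy`), `v`, `q` and
#'   `n_iter`.
#' @export
policy_iteration <- function(mdp, max_iter = NULL) {
  avail <- mdp$available
  any_a <- rowSums(avail) > 0
  max_iter <- max_iter %||% (mdp$n_states * mdp$n_actions + 10L)
  first_avail <- max.col(avail, ties.method = "first") - 1L
  action <- ifelse(any_a, first_avail, NA_integer_)
  v <- NULL; q <- NULL
  for (it in seq_len(max_iter)) {
    pol <- new_policy(action = action, n_states = mdp$n_states,
                      n_actions = mdp$n_actions)
    v <- policy_evaluation(mdp, pol)
    q <- q_from_v(mdp, v)
    qm <- q
    qm[!avail] <- -Inf
    new_action <- max.col(qm, ties.method = "first") - 1L
    new_action[!any_a] <- NA_integer_
    if (identical(new_action, action)) break
    action <- new_action
  }
  list(policy = new_policy(action = action, n_states = mdp$n_states,
                           n_actions = mdp$n_actions),
       v = v, q = q, n_iter = it)
}

#' Empirical clinician (behaviour) policy
#'
#' For each state, the empirical action frequencies over its visits, with
#' add-delta smoothing across the actions observed at least once in that
#' state (`(n_a + delta) / (N + delta * m)`); never-observed actions keep
#' probability zero. States never visited fall back to a uniform
#' distribution over available actions (flagged in
#' `attr(, "unvisited_states")`).
#'
#' @param mdp A `sepsis_mdp` carrying unfiltered counts, or a raw counts
#'   data.frame (`s`, `a`, `n` at minimum).
#' @param n_states,n_actions Required when `mdp` is a counts data.frame.
#' @param delta Smoothing mass per observed action (default 0.01).
#' @param available Optional availability matrix for the unvisited-state
#'   fallback.
#' @return A stochastic `sepsis_policy`.
#' @export
estimate_clinician_policy <- function(mdp, n_states = NULL,
                                      n_actions = 25L, delta = 0.01,
                                      available = NULL) {
  if (inherits(mdp, "sepsis_mdp")) {
    counts <- mdp$counts_raw
    n_states <- mdp$n_states
    n_actions <- mdp$n_actions
    available <- available %||% mdp$available
  } else {
    counts <- mdp
    stopifnot(!is.null(n_states))
  }
  sa <- rowsum(counts$n, counts$s * n_actions + counts$a)
  kk <- as.integer(rownames(sa))
  Nmat <- matrix(0, n_states, n_actions)
  Nmat[cbind(kk %/% n_actions + 1L, kk %% n_actions + 1L)] <- sa[, 1L]
  visits <- rowSums(Nmat)
  m_obs <- rowSums(Nmat > 0)
  P <- matrix(0, n_states, n_actions)
  vis <- visits > 0
  P[vis, ] <- (Nmat[vis, , drop = FALSE] +
                 delta * (Nmat[vis, , drop = FALSE] > 0)) /
    (visits[vis] + delta * m_obs[vis])
  unvisited <- which(!vis)
  clinical_unvisited <- unvisited[unvisited <= n_states - 2L]
  if (length(unvisited) && !is.null(available)) {
    for (s in unvisited) {
      av <- which(available[s, ])
      if (length(av)) P[s, av] <- 1 / length(av)
    }
  }
  pol <- new_policy(prob = P, n_states = n_states, n_actions = n_actions)
  attr(pol, "unvisited_states") <- clinical_unvisited - 1L
  pol
}

#' Temporal-difference configuration
#'
#' @param alpha Initial learning rate in `(0, 1]`.
#' @param n_sweeps Number of passes over the logged transitions.
#' @param alpha_decay Multiplicative learning-rate decay per sweep.
#' @param seed Seed of the per-sweep transition shuffling.
#' @return An object of class `td_config`.
#' @export
td_config <- function(alpha = 0.1, n_sweeps = 200L, alpha_decay = 0.99,
                      seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha, n_sweeps = as.integer(n_sweeps),
                 alpha_decay = alpha_decay, seed = as.integer(seed)),
            class = "td_config")
}

#' Flatten sequences into SARSA tuples
#'
#' @param seqs Logged sequences from [build_sequences()].
#' @return Data.frame `(s, a, r, s2, a2)`; `a2` is `NA` on the terminal
#'   transition (the bootstrap term is 0 there).
#' @export
sequences_to_sarsa <- function(seqs) {
  pieces <- lapply(seqs, function(x) {
    T <- length(x$actions)
    data.frame(s = x$states[seq_len(T)], a = x$actions,
               r = c(rep(0, T - 1L), x$reward),
               s2 = x$states[seq_len(T) + 1L],
               a2 = c(x$actions[-1L], NA_integer_))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Evaluate the behaviour policy by temporal-difference (SARSA) learning
#'
#' Applies `Q(s,a) <- Q(s,a) + alpha (r + gamma Q(s',a') - Q(s,a))` over the
#' logged transitions in randomized order, sweeping repeatedly with a
#' decaying learning rate. The bootstrap term is zero on transitions into an
#' absorbing state. Initialization is `Q = 0`.
#'
#' @param transitions SARSA tuples from [sequences_to_sarsa()].
#' @param n_states,n_actions State/action space sizes.
#' @param gamma Discount factor.
#' @param config A [td_config()].
#' @return Matrix `n_states x n_actions` of learned action values.
#' @export
td_evaluate_clinician <- function(transitions, n_states, n_actions = 25L,
                                  gamma = 0.99, config = td_config()) {
  Q <- matrix(0, n_states, n_actions)
  n <- nrow(transitions)
  if (!n || config$alpha == 0) return(Q)
  s <- transitions$s + 1L; a <- transitions$a + 1L
  s2 <- transitions$s2 + 1L
  a2 <- transitions$a2 + 1L
  r <- transitions$r
  terminal <- is.na(a2)
  with_seed(config$seed, {
    alpha <- config$alpha
    for (sweep in seq_len(config$n_sweeps)) {
      for (i in sample.int(n)) {
        target <- r[i] + if (terminal[i]) 0 else gamma * Q[s2[i], a2[i]]
        Q[s[i], a[i]] <- Q[s[i], a[i]] + alpha * (target - Q[s[i], a[i]])
      }
      alpha <- alpha * config$alpha_decay
    }
  })
  Q
}
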