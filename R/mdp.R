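#' Count one-step transitions from state/action sequences
#'
#' @param seqs List of trajectories as produced by [build_sequences()]:
#'   each `list(states, actions, ...)` with `states` of length `T + 1`
#'   ending in an absorbing id and `actions` of length `T`.
#' @param n_states Total state count `k + 2`.
#' @param n_actions Number of actions (25).
#' @return List with `counts` (data.frame `s`, `a`, `s2`, `n` of observed
#'   triplets) and `d0` (empirical initial-state distribution, length
#'   `n_states`).
#' @export
count_transitions <- function(seqs, n_states, n_actions = 25L) {
  absorbing <- c(n_states - 2L, n_states - 1L)
  s <- integer(0); a <- integer(0); s2 <- integer(0); first <- integer(0)
  if (length(seqs)) {
    s <- unlist(lapply(seqs, function(x) x$states[-length(x$states)]),
                use.names = FALSE)
    s2 <- unlist(lapply(seqs, function(x) x$states[-1L]), use.names = FALSE)
    a <- unlist(lapply(seqs, function(x) x$actions), use.names = FALSE)
    first <- vapply(seqs, function(x) x$states[1L], integer(1))
    if (length(a) != length(s))
      stop_config("each trajectory needs one action per non-terminal state")
    if (any(s %in% absorbing))
      stop("action taken on an absorbing state", call. = FALSE)
    if (any(a < 0L | a >= n_actions))
      stop_config("action id out of range")
  }
  key <- (s * n_actions + a) * n_states + s2
  uk <- sort(unique(key))
  n <- tabulate(match(key, uk), nbins = length(uk))
  counts <- data.frame(s = uk %/% (n_actions * n_states),
                       a = (uk %/% n_states) %% n_actions,
                       s2 = uk %% n_states,
                       n = n)
  d0 <- tabulate(first + 1L, nbins = n_states)
  d0 <- if (length(first)) d0 / length(first) else rep(0, n_states)
  list(counts = counts, d0 = d0)
}

#' Remove rarely observed transitions
#'
#' Transition triplets observed fewer than `threshold` times are dropped;
#' state-action pairs whose total retained count falls to zero become
#' unavailable and are never selected by a learned policy. This restricts the
#' agent to actions commonly taken by clinicians.
#'
#' @param counts Triplet counts data.frame (`s`, `a`, `s2`, `n`).
#' @param threshold Minimum observation count (default 5).
#' @return The filtered counts data.frame.
#' @export
filter_rare_transitions <- function(counts, threshold = 5L) {
  stopifnot(threshold >= 1L)
  out <- counts[counts$n >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize transition counts to probabilities
#'
#' @param counts Triplet counts data.frame (`s`, `a`, `s2`, `n`).
#' @return The data.frame with a `prob` column; each retained `(s, a)` row
#'   group sums to 1.
#' @export
normalize_transitions <- function(counts) {
  if (!nrow(counts))
    stop("no transitions retained; cannot normalize", call. = FALSE)
  tot <- rowsum(counts$n, counts$s * 25L + counts$a)
  counts$prob <- counts$n /
    tot[match(as.character(counts$s * 25L + counts$a), rownames(tot)), 1L]
  counts
}

#' Terminal reward vector
#'
#' Rewards are granted only on entry into an absorbing state: +100 for
#' survival, -100 for death, 0 for every clinical state.
#'
#' @param k Number of clinical states.
#' @return Numeric vector of length `k + 2` indexed by `state id + 1`.
#' @export
reward_vector <- function(k) {
  r <- numeric(k + 2L)
  r[k + 1L] <- 100    # survived (id k)
  r[k + 2L] <- -100   # dead (id k + 1)
  r
}

new_mdp <- function(k, gamma, threshold, trans, counts_raw, d0,
                    n_actions = 25L) {
  n_states <- k + 2L
  available <- matrix(FALSE, n_states, n_actions)
  if (nrow(trans)) available[cbind(trans$s + 1L, trans$a + 1L)] <- TRUE
  structure(list(k = as.integer(k), n_states = n_states,
                 n_actions = as.integer(n_actions),
                 gamma = gamma, threshold = threshold,
                 trans = trans, counts_raw = counts_raw, d0 = d0,
                 reward = reward_vector(k), available = available,
                 survived_id = as.integer(k), dead_id = as.integer(k + 1L)),
            class = "sepsis_mdp")
}

#' Estimate the tabular MDP from logged sequences
#'
#' Counts transitions, filters triplets observed fewer than `threshold`
#' times, and normalizes the retained counts into the transition tensor
#' `T(s', s, a)`. Absorbing states (survival `k`, death `k+1`) self-loop and
#' emit no further reward; states left without any available action fall
#' back to a zero-reward self-transition and are excluded from policy
#' improvement.
#'
#' @param seqs Logged sequences from [build_sequences()].
#' @param k Number of clinical states.
#' @param gamma Discount factor in `(0, 1]` (default 0.99).
#' @param threshold Rare-transition filter threshold (default 5).
#' @return An object of class `sepsis_mdp`.
#' @export
build_mdp <- function(seqs, k, gamma = 0.99, threshold = 5L) {
  stopifnot(gamma > 0, gamma <= 1)
  ct <- count_transitions(seqs, n_states = k + 2L)
  filtered <- filter_rare_transitions(ct$counts, threshold)
  trans <- normalize_transitions(filtered)
  new_mdp(k, gamma, threshold, trans, ct$counts, ct$d0)
}

#' Construct a toy MDP from explicit transition probabilities
#'
#' Intended for small worked examples and simulation studies where the true
#' dynamics are known. Rows are per-`(s, a)` conditional distributions over
#' next states.
#'
#' @param trans Data.frame with columns `s`, `a`, `s2`, `prob`; per `(s, a)`
#'   the probabilities must sum to 1.
#' @param k Number of clinical states (absorbing ids are `k` and `k + 1`).
#' @param gamma Discount factor.
#' @param d0 Initial state distribution (default: uniform over clinical
#'   states).
#' @param n_actions Size of the action space (25 in the treatment grid;
#'   smaller for worked examples).
#' @return An object of class `sepsis_mdp`.
#' @export
mdp_from_probabilities <- function(trans, k, gamma = 0.99, d0 = NULL,
                                   n_actions = 25L) {
  stopifnot(all(c("s", "a", "s2", "prob") %in% names(trans)))
  key <- trans$s * 25L + trans$a
  sums <- rowsum(trans$prob, key)
  if (any(abs(sums - 1) > 1e-9))
    stop_config("transition rows must sum to 1 per (s, a)")
  if (is.null(d0)) d0 <- c(rep(1 / k, k), 0, 0)
  trans$n <- NA_integer_
  new_mdp(k, gamma, NA_integer_, trans,
          counts_raw = trans[0, c("s", "a", "s2", "n")], d0 = d0,
          n_actions = n_actions)
}

#' Restrict an MDP to a subset of actions
#'
#' Used by policy-constrained baselines (e.g. fluid-only dosing): transitions
#' through disallowed actions are removed and availability recomputed; the
#' per-`(s, a)` conditional transition probabilities are unchanged.
#'
#' @param mdp A `sepsis_mdp`.
#' @param allowed_actions Integer vector of permitted action ids.
#' @return The restricted `sepsis_mdp`.
#' @export
restrict_mdp <- function(mdp, allowed_actions) {
  trans <- mdp$trans[mdp$trans$a %in% allowed_actions, , drop = FALSE]
  rownames(trans) <- NULL
  cr <- mdp$counts_raw[mdp$counts_raw$a %in% allowed_actions, , drop = FALSE]
  new_mdp(mdp$k, mdp$gamma, mdp$threshold, trans, cr, mdp$d0,
          n_actions = mdp$n_actions)
}

#' @export
print.sepsis_mdp <- function(x, ...) {
  cat("Tabular MDP:", x$k, "clinical states + 2 absorbing,", x$n_actions,
      "actions, gamma =", x$gamma, "\n")
  cat(nrow(x$trans), "retained transition triplets;",
      sum(x$available), "available (state, action) pairs\n")
  invisible(x)
}
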