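#' Simulate logged trajectories from an MDP under a behaviour policy
#'
#' Used in simulation studies (e.g. consistency checks of off-policy
#' estimators against model-based values): initial states are drawn from
#' `d0`, actions from the behaviour policy, next states from
#' `T(s' | s, a)`; a trajectory ends on entering an absorbing state, where
#' the terminal reward is collected.
#'
#' @param mdp A `sepsis_mdp` (typically from [mdp_from_probabilities()]).
#' @param policy Behaviour `sepsis_policy` (stochastic or deterministic);
#'   must put its mass on available actions.
#' @param n Number of trajectories.
#' @param seed Simulation seed.
#' @param max_steps Safety truncation; a truncated trajectory gets reward 0
#'   and is terminated in the survival state.
#' @return List of trajectories (`list(states, actions, reward)`), the format
#'   [wis_estimate()] and [count_transitions()] accept.
#' @export
simulate_trajectories <- function(mdp, policy, n, seed = 1L,
                                  max_steps = 500L) {
  P <- if (inherits(policy, "sepsis_policy")) policy_matrix(policy)
       else policy
  tr <- mdp$trans
  key <- tr$s * mdp$n_actions + tr$a
  by_sa <- split(seq_len(nrow(tr)), key)
  nexts <- lapply(by_sa, function(i) tr$s2[i])
  cums <- lapply(by_sa, function(i) cumsum(tr$prob[i]))
  keys <- as.integer(names(by_sa))
  absorbing <- c(mdp$survived_id, mdp$dead_id)
  d0 <- mdp$d0
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- sample.int(mdp$n_states, 1L, prob = d0) - 1L
      states <- s; actions <- integer(0); reward <- 0
      for (step in seq_len(max_steps)) {
        pa <- P[s + 1L, ]
        if (sum(pa) <= 0)
          stop("behaviour policy undefined in visited state ", s,
               call. = FALSE)
        a <- sample.int(mdp$n_actions, 1L, prob = pa) - 1L
        ki <- match(s * mdp$n_actions + a, keys)
        if (is.na(ki))
          stop("no transition model for state ", s, " action ", a,
               call. = FALSE)
        u <- stats::runif(1)
        s2 <- nexts[[ki]][findInterval(u, cums[[ki]], left.open = TRUE) + 1L]
        actions <- c(actions, a)
        states <- c(states, s2)
        if (s2 %in% absorbing) {
          reward <- mdp$reward[s2 + 1L]
          break
        }
        s <- s2
      }
      if (!states[length(states)] %in% absorbing) {
        states[length(states)] <- mdp$survived_id  # truncated: no reward
        reward <- 0
      }
      list(states = states, actions = actions, reward = reward)
    })
  })
}
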