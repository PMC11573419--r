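# Weighted importance sampling, bootstrap lower bounds, constrained
# baselines, and the value/mortality calibration curve.

traj <- function(states, actions, reward)
  list(states = as.integer(states), actions = as.integer(actions),
       reward = reward)

test_that("cumulative importance ratios multiply per-step likelihood ratios", {
  Pa <- rbind(c(0.8, 0.2), c(0.5, 0.5), 0, 0)
  Pc <- rbind(c(0.4, 0.6), c(0.5, 0.5), 0, 0)
  x <- traj(c(0, 1, 2), c(0, 0), 100)
  expect_equal(importance_ratios(x, Pa, Pa), c(1, 1))      # identity
  expect_equal(importance_ratios(x, Pa, Pc), c(2, 2))      # 2 then 1
  y <- traj(c(0, 0, 2), c(0, 1), 100)
  expect_equal(importance_ratios(y, Pa, Pc), c(2, 2 / 3))  # 2 then 1/3
  Pz <- rbind(c(1, 0), c(1, 0), 0, 0)
  expect_error(importance_ratios(y, Pa, Pz), "zero probability")
})

test_that("softening keeps p_greedy on the chosen action and spreads the
           rest over available alternatives", {
  avail <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, FALSE),
                 rep(FALSE, 3), rep(FALSE, 3))
  pol <- new_policy(action = c(1L, 0L, NA, NA), n_states = 4L,
                    n_actions = 3L)
  soft <- soften_policy(pol, avail, p_greedy = 0.99)
  expect_equal(soft$prob[1, ], c(0.005, 0.99, 0.005))
  expect_equal(soft$prob[2, ], c(1, 0, 0))  # single available action
  # hand oracle for the ratio of a non-greedy logged action
  Pc <- matrix(0.5, 4, 3)
  x <- traj(c(0, 2), 0, 100)
  expect_equal(importance_ratios(x, soft$prob, Pc), 0.005 / 0.5)
})

test_that("WIS self-evaluation returns the empirical mean discounted return", {
  set.seed(4)
  trajs <- lapply(1:40, function(i) {
    T <- sample(1:6, 1)
    traj(c(sample(0:1, T, TRUE), sample(2:3, 1)), sample(0:1, T, TRUE),
         sample(c(100, -100), 1))
  })
  Pc <- rbind(c(0.3, 0.7), c(0.6, 0.4), 0, 0)
  gamma <- 0.97
  res <- wis_estimate(trajs, Pc, Pc, gamma)
  ret <- vapply(trajs, function(x)
    gamma^(length(x$actions) - 1) * x$reward, numeric(1))
  expect_equal(res$estimate, mean(ret), tolerance = 1e-12)
  # single-trajectory self-normalization cancels the ratios entirely
  Pa <- rbind(c(0.9, 0.1), c(0.2, 0.8), 0, 0)
  one <- wis_estimate(trajs[1], Pa, Pc, gamma)
  expect_equal(one$estimate, ret[1], tolerance = 1e-12)
})

test_that("scaling every cumulative ratio by a constant leaves WIS
           unchanged (self-normalization)", {
  set.seed(9)
  trajs <- lapply(1:25, function(i) {
    T <- sample(1:5, 1)
    traj(c(sample(0:1, T, TRUE), 2), sample(0:1, T, TRUE), sample(c(100, -100), 1))
  })
  Pc <- rbind(c(0.5, 0.5), c(0.25, 0.75), 0, 0)
  Pa <- rbind(c(0.8, 0.2), c(0.5, 0.5), 0, 0)
  prep <- sepsisrl:::wis_prepare(trajs, Pa, Pc, 1)
  base <- sepsisrl:::wis_from_prep(prep)$wis
  for (const in c(0.2, 5, 40)) {
    prep2 <- prep
    prep2$rho <- prep$rho * const
    expect_equal(sepsisrl:::wis_from_prep(prep2)$wis, base,
                 tolerance = 1e-10)
  }
  # for equal-horizon trajectories the same holds through the public API
  eqh <- Filter(function(x) length(x$actions) == 2L, trajs)
  if (length(eqh) >= 2) {
    expect_equal(wis_estimate(eqh, Pa, Pc, 1)$estimate,
                 wis_estimate(eqh, Pa, Pc / 5, 1)$estimate,
                 tolerance = 1e-10)
  }
})

test_that("three-trajectory worked example matches the hand computation", {
  Pa <- rbind(c(0.8, 0.2), c(0.5, 0.5), 0, 0)
  Pc <- rbind(c(0.4, 0.6), c(0.5, 0.5), 0, 0)
  trajs <- list(traj(c(0, 1, 2), c(0, 0), 100),   # rho (2, 2), survives
                traj(c(0, 3), 1, -100),           # rho (1/3), dies
                traj(c(1, 0, 2), c(1, 0), 100))   # rho (1, 2), survives
  # w1 = mean(2, 1/3, 1) = 10/9; w2 = mean(2, 1/3, 2) = 13/9 (frozen rho)
  # V = (2/(13/9))*100, (1/3)/(10/9)*(-100), (2/(13/9))*100
  res <- wis_estimate(trajs, Pa, Pc, gamma = 1)
  expect_equal(res$v_wis, c(1800 / 13, -30, 1800 / 13), tolerance = 1e-12)
  expect_equal(res$estimate, 1200 / 13 - 10, tolerance = 1e-12)
})

test_that("bootstrap bounds are ordered percentiles of the resampled WIS", {
  # degenerate case: identical surviving trajectories
  trajs <- rep(list(traj(c(0, 2), 0, 100)), 10)
  Pc <- rbind(c(1, 0), c(0.5, 0.5), 0, 0)
  res <- bootstrap_wis(trajs, Pc, Pc, gamma = 1, B = 50, seed = 1)
  expect_equal(res$mean_value, 100)
  expect_equal(res$lb95, 100)
  expect_equal(res$lb99, 100)

  # B = 1: both bounds equal that single resample's estimate
  set.seed(2)
  trajs2 <- lapply(1:15, function(i)
    traj(c(0, sample(2:3, 1)), 0, sample(c(100, -100), 1)))
  r1 <- bootstrap_wis(trajs2, Pc, Pc, gamma = 1, B = 1, seed = 3)
  expect_equal(r1$lb95, r1$bootstrap[1])
  expect_equal(r1$lb99, r1$bootstrap[1])

  r2 <- bootstrap_wis(trajs2, Pc, Pc, gamma = 0.99, B = 400, seed = 5)
  expect_lte(r2$lb99, r2$lb95)
  expect_lte(r2$lb95, max(r2$bootstrap))
  expect_lte(r2$lb95, r2$mean_value)
  expect_true(all(abs(r2$bootstrap) <= 100))
})

test_that("bootstrap matches an independent reference implementation", {
  set.seed(11)
  trajs <- lapply(1:20, function(i) {
    T <- sample(1:4, 1)
    traj(c(sample(0:1, T, TRUE), sample(2:3, 1)), sample(0:1, T, TRUE),
         sample(c(100, -100), 1))
  })
  Pa <- rbind(c(0.7, 0.3), c(0.4, 0.6), 0, 0)
  Pc <- rbind(c(0.5, 0.5), c(0.5, 0.5), 0, 0)
  res <- bootstrap_wis(trajs, Pa, Pc, gamma = 0.95, B = 300, seed = 17)
  ref <- wis_reference(trajs, Pa, Pc, gamma = 0.95, B = 300, seed = 17)
  expect_equal(res$estimate, ref$estimate, tolerance = 1e-12)
  expect_equal(res$bootstrap, ref$boot, tolerance = 1e-12)
  expect_equal(res$lb95, ref$lb95, tolerance = 1e-12)
  expect_equal(res$lb99, ref$lb99, tolerance = 1e-12)
})

test_that("constrained baseline policies have the stated structure", {
  mdp <- random_mdp(4, n_actions = 25L, seed = 8, gamma = 0.99)
  beh <- estimate_clinician_policy(
    data.frame(s = rep(0:3, each = 25), a = rep(0:24, 4), s2 = 4L, n = 2L),
    n_states = 6L, n_actions = 25L)
  trajs <- simulate_trajectories(mdp, beh, n = 50, seed = 2)
  out <- evaluate_constrained_policies(mdp, trajs, beh, gamma = 0.99,
                                       B = 50, seed = 4)
  pols <- attr(out, "policies")
  expect_named(out, c("RAND", "NO_DRUGS", "NO_VASOPRESSORS", "NO_FLUID"))
  # NO_VASOPRESSORS puts no mass on any action with a nonzero vaso bin
  vaso_bin <- (0:24) %/% 5L
  expect_true(all(pols$NO_VASOPRESSORS$prob[, vaso_bin > 0] == 0))
  expect_true(all(pols$NO_FLUID$prob[, (0:24) %% 5L > 0] == 0))
  expect_equal(max.col(pols$NO_DRUGS$prob[1:4, ]), rep(1L, 4))
  rs <- rowSums(pols$RAND$prob[1:4, ])
  expect_true(all(abs(rs - 1) < 1e-12))
  for (r in out) expect_lte(r$lb99, r$lb95)
})

test_that("degenerate behaviours reduce WIS to the behaviour mean return", {
  # only action 0 ever taken and available: NO DRUGS equals behaviour value,
  # and RAND with a single available action equals the deterministic policy
  trans <- data.frame(s = 0L, a = 0L, s2 = c(1L, 2L), prob = c(0.8, 0.2))
  mdp <- mdp_from_probabilities(trans, k = 1L, gamma = 1,
                                d0 = c(1, 0, 0), n_actions = 25L)
  beh <- new_policy(prob = {
    P <- matrix(0, 3, 25); P[1, 1] <- 1; P
  }, n_states = 3L, n_actions = 25L)
  trajs <- simulate_trajectories(mdp, beh, n = 60, seed = 9)
  ret <- mean(vapply(trajs, function(x) x$reward, numeric(1)))
  out <- evaluate_constrained_policies(mdp, trajs, beh, gamma = 1,
                                       B = 30, seed = 1)
  expect_equal(out$NO_DRUGS$estimate, ret, tolerance = 1e-12)
  expect_equal(out$RAND$estimate, ret, tolerance = 1e-12)
})

test_that("calibration curve bins values and reports per-bin mortality", {
  cc <- calibration_curve(rep(100, 5), rep(FALSE, 5))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$value_mid, 90)
  expect_equal(cc$mortality, 0)

  cc2 <- calibration_curve(c(rep(-100, 4), rep(100, 6)),
                           c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(cc2$mortality, c(1, 0))
  expect_equal(cc2$n, c(4L, 6L))
  expect_equal(cc2$value_mid, c(-90, 90))
})

test_that("mortality decreases across model-value bins on synthetic data", {
  fx <- small_pipeline_fixture()
  res <- run_trial(fx$traj, "FULL", k = 15, seed = 5, B = 50)
  test_rows <- fx$traj[fx$traj$split == "test", ]
  first <- test_rows[!duplicated(test_rows$patient_id), ]
  st <- assign_states(first, res$state_model)
  v_c <- policy_evaluation(res$mdp, res$pi_c)
  vals <- v_c[st + 1L]
  died <- first$died_90d
  cc <- calibration_curve(vals, died, n_bins = 10)
  cc <- cc[cc$n >= 5, ]
  expect_lte(stats::cor(cc$value_mid, cc$mortality, method = "spearman"), 0)
})
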