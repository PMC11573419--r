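# State discretization (feature sets, PCA, k-means++) and the 25-level
# action grid.

test_that("a-priori feature sets subset the stated columns in order", {
  fx <- small_pipeline_fixture()
  red <- select_features(fx$traj, feature_set_spec("CARDIO"))
  expect_identical(attr(red, "feature_names"), cardio_features())
  expect_identical(names(red)[3:8], cardio_features())
  full <- select_features(fx$traj, feature_set_spec("FULL"))
  expect_length(attr(full, "feature_names"), 48L)
  expect_length(attr(select_features(fx$traj, feature_set_spec("NO_LAB")),
                     "feature_names"), 22L)
  expect_identical(attr(select_features(fx$traj,
                                        feature_set_spec("BASELINE")),
                        "feature_names"), baseline_features())
  bad <- feature_set_spec("CUSTOM", features = c("heart_rate", "nope"))
  expect_error(select_features(fx$traj, bad), "unknown feature")
})

test_that("PCA sets keep the fixed component counts and explain the
           variance a direct eigendecomposition attributes to them", {
  fx <- small_pipeline_fixture()
  red <- select_features(fx$traj, feature_set_spec("PCA80"))
  expect_length(attr(red, "feature_names"), 25L)
  tf <- attr(red, "transform")
  expect_gte(tf$explained_variance[25], 0.80)

  # oracle: eigenvalues of the training correlation-scaled covariance
  X <- as.matrix(fx$traj[, default_feature_names()])
  tr <- fx$traj$split == "train"
  Z <- scale(X[tr, ], center = tf$center, scale = tf$scale)
  ev <- sort(eigen(stats::cov(Z) * (sum(tr) - 1) / sum(tr),
                   symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  # prcomp divides by n-1; rescale to match
  ev <- ev * sum(tr) / (sum(tr) - 1)
  expect_equal(tf$explained_variance[1:25],
               (cumsum(ev) / sum(ev))[1:25], tolerance = 1e-6)

  expect_length(attr(select_features(fx$traj, feature_set_spec("PCA15")),
                     "feature_names"), 2L)
})

test_that("PCA and the standardizer are fitted on the training split only", {
  fx <- small_pipeline_fixture()
  traj <- fx$traj
  m1 <- fit_state_model(traj, feature_set_spec("PCA15"), k = 5, seed = 3)
  traj2 <- traj
  test_rows <- which(traj2$split == "test")
  for (f in default_feature_names())  # scramble the test rows entirely
    traj2[[f]][test_rows] <- rev(traj2[[f]][test_rows]) + 17
  m2 <- fit_state_model(traj2, feature_set_spec("PCA15"), k = 5, seed = 3)
  expect_identical(m1$centroids, m2$centroids)
  expect_identical(m1$center, m2$center)
  expect_identical(m1$rotation, m2$rotation)
})

test_that("degenerate and separable clusterings behave analytically", {
  df <- data.frame(patient_id = 1:40, bin_index = 0L,
                   x = c(rnorm(20), rnorm(20) + 50),
                   y = c(rnorm(20), rnorm(20) + 50),
                   died_90d = FALSE, split = "train")
  class(df) <- c("trajectory_table", "data.frame")
  attr(df, "feature_names") <- c("x", "y")
  spec <- feature_set_spec("CUSTOM", features = c("x", "y"))

  m1 <- fit_state_model(df, spec, k = 1, seed = 1)
  expect_equal(drop(m1$centroids), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)  # standardized train mean
  expect_equal(m1$survived_id, 1L)
  expect_equal(m1$dead_id, 2L)

  m2 <- fit_state_model(df, spec, k = 2, seed = 1)
  st <- assign_states(df, m2)
  expect_length(unique(st[1:20]), 1L)     # each blob in one cluster
  expect_length(unique(st[21:40]), 1L)
  expect_false(st[1] == st[21])

  expect_error(fit_state_model(df, spec, k = 100, seed = 1),
               "fewer training rows")
})

test_that("k-means++ with Lloyd matches a multi-restart oracle on a fixed
           30-point set", {
  set.seed(10)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2),
               matrix(rnorm(20, 6), 10, 2),
               matrix(rnorm(20, c(0, 12)), 10, 2))
  df <- data.frame(patient_id = 1:30, bin_index = 0L,
                   x = pts[, 1], y = pts[, 2], died_90d = FALSE,
                   split = "train")
  class(df) <- c("trajectory_table", "data.frame")
  attr(df, "feature_names") <- c("x", "y")
  spec <- feature_set_spec("CUSTOM", features = c("x", "y"))
  m <- fit_state_model(df, spec, k = 3, seed = 4)
  Z <- scale(pts, center = m$center, scale = m$scale)
  st <- assign_states(df, m)
  wss <- sum((Z - m$centroids[st + 1L, ])^2)
  oracle <- suppressWarnings(stats::kmeans(Z, centers = 3, nstart = 50,
                                           iter.max = 100))
  expect_lt(wss - oracle$tot.withinss, 1e-6)
})

test_that("state assignment is nearest-centroid with lowest-index ties and
           sequences end in the outcome's absorbing state", {
  m <- structure(list(k = 3L, spec = feature_set_spec("CUSTOM",
                                                      features = c("x", "y")),
                      features = c("x", "y"),
                      center = c(x = 0, y = 0), scale = c(x = 1, y = 1),
                      rotation = NULL,
                      centroids = rbind(c(0, 0), c(4, 0), c(2, 0)),
                      seed = 1L, survived_id = 3L, dead_id = 4L),
                 class = "state_model")
  df <- data.frame(patient_id = c(1, 1, 1, 2), bin_index = c(0, 1, 2, 0),
                   x = c(4, 2, 1, 0), y = 0,
                   vaso_dose = 0, fluid_volume = 100,
                   died_90d = c(FALSE, FALSE, FALSE, TRUE))
  class(df) <- c("trajectory_table", "data.frame")
  attr(df, "feature_names") <- c("x", "y")
  st <- assign_states(df, m)
  expect_equal(st[1], 1L)  # exactly on centroid 1
  expect_equal(st[2], 2L)  # exactly on centroid 2
  expect_equal(st[3], 0L)  # equidistant from centroids 0 and 2 -> lowest
  grid <- structure(list(vaso_edges = c(1, 2, 3),
                         fluid_edges = c(50, 100, 150)),
                    class = "action_grid")
  seqs <- build_sequences(df, m, grid)
  expect_length(seqs[["1"]]$states, 4L)
  expect_equal(tail(seqs[["1"]]$states, 1), 3L)   # survivor -> id k
  expect_equal(seqs[["1"]]$reward, 100)
  expect_equal(tail(seqs[["2"]]$states, 1), 4L)   # death -> id k+1
  expect_equal(seqs[["2"]]$reward, -100)
})

test_that("action grid edges are the nonzero-dose quartiles and bins are
           right-closed with a reserved null bin", {
  grid <- fit_action_grid(vaso = c(0, 0, 2, 4, 6, 8),
                          fluid = c(0, 100, 200, 300, 400))
  # quantile(c(2,4,6,8), c(.25,.5,.75), type 7) = 3.5, 5, 6.5
  expect_equal(grid$vaso_edges, c(3.5, 5, 6.5))
  expect_equal(dose_to_bin(0, grid$vaso_edges), 0L)
  expect_equal(dose_to_bin(2, grid$vaso_edges), 1L)
  expect_equal(dose_to_bin(5, grid$vaso_edges), 2L)    # edge -> lower bin
  expect_equal(dose_to_bin(6.5, grid$vaso_edges), 3L)
  expect_equal(dose_to_bin(100, grid$vaso_edges), 4L)  # above e75
  expect_equal(action_id(3L, 1L), 16L)
  expect_error(fit_action_grid(vaso = c(0, 0), fluid = c(1, 2)),
               "all vasopressor doses are zero")
})

test_that("every nonnegative dose pair maps to exactly one of 25 actions", {
  grid <- fit_action_grid(vaso = runif(50), fluid = runif(50) * 500)
  v <- c(0, runif(200) * 2)
  f <- c(0, runif(200) * 1000)
  ids <- action_id(dose_to_bin(v, grid$vaso_edges),
                   dose_to_bin(f, grid$fluid_edges))
  expect_true(all(ids >= 0L & ids < 25L))
  expect_length(ids, 201L)
  # inverse consistency: id decomposes back into the bins
  expect_equal(ids %/% 5L, dose_to_bin(v, grid$vaso_edges))
  expect_equal(ids %% 5L, dose_to_bin(f, grid$fluid_edges))
})

test_that("refitting with the same seed reproduces the model bit for bit", {
  fx <- small_pipeline_fixture()
  m1 <- fit_state_model(fx$traj, feature_set_spec("CARDIO"), k = 20,
                        seed = 11)
  m2 <- fit_state_model(fx$traj, feature_set_spec("CARDIO"), k = 20,
                        seed = 11)
  expect_identical(m1$centroids, m2$centroids)
  st1 <- assign_states(fx$traj, m1)
  expect_identical(st1, assign_states(fx$traj, m2))
  expect_true(all(st1 >= 0L & st1 < 20L))
  m3 <- fit_state_model(fx$traj, feature_set_spec("CARDIO"), k = 20,
                        seed = 12)
  expect_false(identical(m1$centroids, m3$centroids))
})
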