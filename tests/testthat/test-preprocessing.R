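# Cohort-definition rules and temporal harmonization, checked on
# hand-constructed event/observation tables.

events_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(patient_id = r[[1]], event_time = r[[2]], event_type = r[[3]],
               stringsAsFactors = FALSE)))
}

test_that("sepsis onset follows the sampling/antibiotic timing rule", {
  ev <- events_df(list(1, 10, "micro_sample"), list(1, 40, "antibiotic"),
                  list(2, 10, "antibiotic"), list(2, 20, "micro_sample"),
                  list(3, 0, "micro_sample"), list(3, 100, "antibiotic"))
  on <- identify_sepsis_onset(ev)
  expect_equal(on$onset_h[on$patient_id == 1], 10)   # sample-first, <=72 h
  expect_equal(on$onset_h[on$patient_id == 2], 10)   # antibiotic-first, <=24 h
  expect_true(is.na(on$onset_h[on$patient_id == 3])) # gap > 72 h
})

test_that("onset takes the earliest qualifying pair and ignores row order", {
  ev <- events_df(list(1, 50, "micro_sample"), list(1, 60, "antibiotic"),
                  list(1, 30, "antibiotic"), list(1, 35, "micro_sample"))
  on1 <- identify_sepsis_onset(ev)
  expect_equal(on1$onset_h, 30)
  set.seed(1)
  on2 <- identify_sepsis_onset(ev[sample.int(nrow(ev)), ])
  expect_identical(on1, on2)
})

test_that("onset boundaries: 72 h sample-first limit, (0, 24] antibiotic-first", {
  on <- identify_sepsis_onset(events_df(list(1, 0, "micro_sample"),
                                        list(1, 72, "antibiotic")))
  expect_equal(on$onset_h, 0)
  on <- identify_sepsis_onset(events_df(list(1, 0, "antibiotic"),
                                        list(1, 24, "micro_sample")))
  expect_equal(on$onset_h, 0)
  on <- identify_sepsis_onset(events_df(list(1, 0, "antibiotic"),
                                        list(1, 24.5, "micro_sample")))
  expect_true(is.na(on$onset_h))
})

toy_raw <- function(outcomes, events) {
  structure(list(observations = data.frame(patient_id = integer(),
                                           bin_index = integer(),
                                           time_h = numeric(),
                                           feature = character(),
                                           value = numeric()),
                 doses = data.frame(patient_id = integer(),
                                    bin_index = integer(), time_h = numeric(),
                                    vaso_dose = numeric(),
                                    fluid_volume = numeric()),
                 outcomes = outcomes, events = events),
            class = "raw_cohort")
}

test_that("exclusions drop minors, undocumented patients and non-septic", {
  oc <- data.frame(patient_id = 1:5, died_90d = FALSE,
                   outcome_documented = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                   fluids_documented = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                   age = c(17.9, 18.0, 40, 40, 40))
  ev <- do.call(rbind, lapply(1:4, function(p)
    events_df(list(p, 10, "micro_sample"), list(p, 20, "antibiotic"))))
  ev <- rbind(ev, events_df(list(5, 0, "micro_sample"),
                            list(5, 100, "antibiotic")))
  raw <- toy_raw(oc, ev)
  kept <- apply_exclusions(raw, identify_sepsis_onset(ev))
  expect_equal(kept$outcomes$patient_id, 2L)  # 1 minor, 3/4 undocumented,
                                              # 5 no qualifying onset
})

test_that("identity exclusion keeps an all-qualifying toy cohort", {
  oc <- data.frame(patient_id = 1:10, died_90d = FALSE,
                   outcome_documented = TRUE, fluids_documented = TRUE,
                   age = 50)
  ev <- do.call(rbind, lapply(1:10, function(p)
    events_df(list(p, 5, "micro_sample"), list(p, 10, "antibiotic"))))
  kept <- apply_exclusions(toy_raw(oc, ev), identify_sepsis_onset(ev))
  expect_equal(nrow(kept$outcomes), 10L)
})

test_that("withdrawal filter needs all three clauses", {
  oc <- data.frame(patient_id = 1:3, died_90d = c(TRUE, TRUE, FALSE),
                   outcome_documented = TRUE, fluids_documented = TRUE,
                   age = 50)
  ev <- rbind(
    # p1: died 10 h after record end, last vaso 30 h before end, one earlier
    events_df(list(1, 100, "record_end"), list(1, 110, "death_time"),
              list(1, 70, "vaso_admin"), list(1, 20, "vaso_admin")),
    # p2: same but a vaso administration 5 h before record end
    events_df(list(2, 100, "record_end"), list(2, 110, "death_time"),
              list(2, 95, "vaso_admin"), list(2, 20, "vaso_admin")),
    # p3: survivor with the same vaso pattern as p1
    events_df(list(3, 100, "record_end"), list(3, 70, "vaso_admin"),
              list(3, 20, "vaso_admin")))
  kept <- apply_withdrawal_filter(toy_raw(oc, ev))
  expect_setequal(kept$outcomes$patient_id, c(2L, 3L))
})

make_obs_raw <- function(obs, doses = NULL, died = FALSE) {
  pid <- unique(obs$patient_id)
  if (is.null(doses))
    doses <- data.frame(patient_id = integer(), bin_index = integer(),
                        time_h = numeric(), vaso_dose = numeric(),
                        fluid_volume = numeric())
  structure(list(
    observations = obs, doses = doses,
    outcomes = data.frame(patient_id = pid, died_90d = died,
                          outcome_documented = TRUE,
                          fluids_documented = TRUE, age = 50),
    events = do.call(rbind, lapply(pid, function(p)
      events_df(list(p, 24, "micro_sample"), list(p, 30, "antibiotic"))))),
    class = "raw_cohort")
}

test_that("binning aggregates by declared rule and drops out-of-window rows", {
  obs <- data.frame(
    patient_id = 1L, bin_index = 0L,
    time_h = c(1, 3, 1, 3, 73.5),
    feature = c("heart_rate", "heart_rate", "total_fluid_input",
                "total_fluid_input", "heart_rate"),
    value = c(80, 90, 200, 300, 120), stringsAsFactors = FALSE)
  raw <- make_obs_raw(obs)
  on <- identify_sepsis_onset(raw$events)  # onset 24 -> window [0, 72)
  tt <- bin_and_aggregate(raw, on, preprocess_config())
  expect_equal(tt$heart_rate[tt$bin_index == 0], 85)        # mean rule
  expect_equal(tt$total_fluid_input[tt$bin_index == 0], 500) # sum rule
  expect_false(any(tt$bin_index > 17))                       # onset+49 h gone
})

test_that("within-bin doses use mean rate for vasopressor, sum for fluid", {
  obs <- data.frame(patient_id = 1L, bin_index = 0L, time_h = 1,
                    feature = "heart_rate", value = 80,
                    stringsAsFactors = FALSE)
  doses <- data.frame(patient_id = 1L, bin_index = 0L, time_h = c(1, 3),
                      vaso_dose = c(0.2, 0.4), fluid_volume = c(100, 150))
  tt <- bin_and_aggregate(make_obs_raw(obs, doses),
                          identify_sepsis_onset(make_obs_raw(obs)$events),
                          preprocess_config())
  expect_equal(tt$vaso_dose[1], 0.3)
  expect_equal(tt$fluid_volume[1], 250)
})

test_that("binning errors on a feature without an aggregation rule", {
  obs <- data.frame(patient_id = 1L, bin_index = 0L, time_h = 1,
                    feature = "mystery", value = 1, stringsAsFactors = FALSE)
  raw <- make_obs_raw(obs)
  expect_error(bin_and_aggregate(raw, identify_sepsis_onset(raw$events),
                                 preprocess_config()),
               "no aggregation rule")
})

make_traj <- function(df, feats) {
  class(df) <- c("trajectory_table", "data.frame")
  attr(df, "feature_names") <- feats
  df
}

test_that("capping clamps into bounds and is idempotent", {
  tt <- make_traj(data.frame(patient_id = 1, bin_index = 0:2,
                             heart_rate = c(300, 85, 10),
                             spo2 = c(-1, 98, 101)),
                  c("heart_rate", "spo2"))
  cfg <- preprocess_config(cap_bounds = list(heart_rate = c(20, 220),
                                             spo2 = c(0, 100)))
  capped <- cap_values(tt, cfg)
  expect_equal(capped$heart_rate, c(220, 85, 20))
  expect_equal(capped$spo2, c(0, 98, 100))
  expect_equal(cap_values(capped, cfg), capped)
})

test_that("imputation forward-fills, back-fills, then falls back to medians", {
  tt <- make_traj(data.frame(
    patient_id = rep(c(1, 2, 3), each = 5), bin_index = rep(0:4, 3),
    x = c(5, NA, NA, 7, NA,   NA, NA, 3, NA, NA,   NA, NA, NA, NA, NA),
    split = "train"), "x")
  out <- impute_trajectories(tt)
  expect_equal(out$x[out$patient_id == 1], c(5, 5, 5, 7, 7))
  expect_equal(out$x[out$patient_id == 2], c(3, 3, 3, 3, 3))
  # patient 3 never observed: training median of {5, 7, 3} = 5
  expect_equal(out$x[out$patient_id == 3], rep(5, 5))
  expect_false(anyNA(out$x))
  expect_equal(impute_trajectories(out), out, ignore_attr = TRUE)
})

test_that("imputation never borrows across patients or from the test split", {
  tt <- make_traj(data.frame(
    patient_id = rep(c(1, 2), each = 3), bin_index = rep(0:2, 2),
    x = c(9, NA, NA, NA, 2, NA),
    split = rep(c("train", "test"), each = 3)), "x")
  out <- impute_trajectories(tt)
  expect_equal(out$x[out$patient_id == 1], c(9, 9, 9))
  expect_equal(out$x[out$patient_id == 2], c(2, 2, 2))  # own series only
  # a feature observed only in the test split has no training median
  tt2 <- make_traj(data.frame(patient_id = c(1, 2), bin_index = 0,
                              x = c(NA, 2),
                              split = c("train", "test")), "x")
  expect_error(impute_trajectories(tt2), "observed nowhere")
})

test_that("train/test split is by patient, deterministic, near 80/20", {
  tt <- make_traj(data.frame(patient_id = rep(1:10, each = 3),
                             bin_index = rep(0:2, 10), x = 1), "x")
  cfg <- preprocess_config(split_seed = 7)
  s1 <- split_train_test(tt, cfg)
  expect_equal(sum(tapply(s1$split, s1$patient_id, unique) == "train"), 8L)
  # bins of one patient never straddle the split
  expect_true(all(tapply(s1$split, s1$patient_id,
                         function(x) length(unique(x))) == 1L))
  expect_identical(split_train_test(tt, cfg)$split, s1$split)
  tt2 <- make_traj(data.frame(patient_id = rep(1:100, each = 2),
                              bin_index = rep(0:1, 100), x = 1), "x")
  a <- split_train_test(tt2, preprocess_config(split_seed = 42))$split
  b <- split_train_test(tt2, preprocess_config(split_seed = 43))$split
  expect_false(identical(a, b))  # verified once: adjacent seeds differ
})

test_that("full preprocessing of a synthetic cohort leaves no gaps", {
  fx <- small_pipeline_fixture()
  tt <- fx$traj
  feats <- attr(tt, "feature_names")
  expect_length(feats, 48L)
  expect_false(anyNA(as.matrix(tt[, feats])))
  expect_true(all(tt$split %in% c("train", "test")))
  # consecutive bins per patient
  gaps <- tapply(tt$bin_index, tt$patient_id,
                 function(b) all(diff(sort(b)) == 1))
  expect_true(all(gaps))
  # capped features inside bounds
  cb <- default_cap_bounds()
  for (f in c("heart_rate", "spo2", "lactate"))
    expect_true(all(tt[[f]] >= cb[[f]][1] & tt[[f]] <= cb[[f]][2]))
})
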