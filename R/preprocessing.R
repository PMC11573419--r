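#' Preprocessing configuration
#'
#' @param bin_hours Width of a time bin in hours.
#' @param window_before_onset_h,window_after_onset_h Analysis window around
#'   sepsis onset, in hours (bin 0 starts at onset minus
#'   `window_before_onset_h`).
#' @param cap_bounds Named list mapping feature to `c(low, high)` plausible
#'   physiological bounds (native units).
#' @param aggregation Named character vector mapping feature to `"mean"` or
#'   `"sum"` for within-bin aggregation.
#' @param train_fraction Fraction of patients assigned to the training split.
#' @param split_seed Seed of the patient-level train/test split.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(bin_hours = 4L,
                              window_before_onset_h = 24L,
                              window_after_onset_h = 48L,
                              cap_bounds = default_cap_bounds(),
                              aggregation = default_aggregation(),
                              train_fraction = 0.8,
                              split_seed = 42L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must lie in (0, 1)")
  bad <- vapply(cap_bounds, function(b) b[1] >= b[2], logical(1))
  if (any(bad))
    stop_config("cap bounds must satisfy low < high: ",
                paste(names(cap_bounds)[bad], collapse = ", "))
  structure(list(bin_hours = as.integer(bin_hours),
                 window_before_onset_h = as.integer(window_before_onset_h),
                 window_after_onset_h = as.integer(window_after_onset_h),
                 cap_bounds = cap_bounds, aggregation = aggregation,
                 train_fraction = train_fraction,
                 split_seed = as.integer(split_seed)),
            class = "preprocess_config")
}

#' Identify sepsis onset from antibiotic / microbiological sampling events
#'
#' A patient qualifies if either (a) a microbiological sampling precedes an
#' antibiotic administration given no more than 72 h later, or (b) a
#' microbiological sampling occurs within 24 h after a previous antibiotic
#' administration. The onset is the time of the earliest event of the
#' earliest qualifying pair.
#'
#' @param events Data.frame with columns `patient_id`, `event_time` (hours)
#'   and `event_type` (at least `"micro_sample"` and `"antibiotic"` rows are
#'   used).
#' @return Data.frame (patient_id, onset_h) over all patients present in
#'   `events`; `onset_h` is `NA` when no pair qualifies.
#' @export
identify_sepsis_onset <- function(events) {
  stopifnot(all(c("patient_id", "event_time", "event_type") %in%
                  names(events)))
  pts <- sort(unique(events$patient_id))
  micro <- events[events$event_type == "micro_sample",
                  c("patient_id", "event_time")]
  anti <- events[events$event_type == "antibiotic",
                 c("patient_id", "event_time")]
  names(micro)[2] <- "t_micro"; names(anti)[2] <- "t_anti"
  onset <- rep(NA_real_, length(pts))
  if (nrow(micro) && nrow(anti)) {
    pairs <- merge(micro, anti, by = "patient_id")
    if (nrow(pairs)) {
      d <- pairs$t_anti - pairs$t_micro
      qual <- (d >= 0 & d <= 72) | (d < 0 & -d <= 24)
      pairs <- pairs[qual, , drop = FALSE]
      if (nrow(pairs)) {
        cand <- pmin(pairs$t_micro, pairs$t_anti)
        best <- tapply(cand, pairs$patient_id, min)
        onset[match(as.numeric(names(best)), pts)] <- as.numeric(best)
      }
    }
  }
  data.frame(patient_id = pts, onset_h = onset)
}

keep_patients <- function(raw, keep_ids) {
  for (tb in c("observations", "doses", "outcomes", "events", "latents")) {
    if (!is.null(raw[[tb]]))
      raw[[tb]] <- raw[[tb]][raw[[tb]]$patient_id %in% keep_ids, ,
                             drop = FALSE]
  }
  raw
}

#' Apply the cohort exclusion rules
#'
#' Retains patients with an identified sepsis onset, age at least 18 years,
#' and documented mortality and intravenous fluid administration.
#'
#' @param raw A `raw_cohort`.
#' @param onsets Output of [identify_sepsis_onset()].
#' @return The filtered `raw_cohort`.
#' @export
apply_exclusions <- function(raw, onsets) {
  oc <- raw$outcomes
  on <- onsets$onset_h[match(oc$patient_id, onsets$patient_id)]
  keep <- !is.na(on) & oc$age >= 18 & oc$outcome_documented &
    oc$fluids_documented
  keep_patients(raw, oc$patient_id[keep])
}

#' Exclude patients whose treatment was withdrawn
#'
#' A withdrawal is a patient who died within 24 h from the end of data
#' recording, received no vasopressor during the final 24 recorded hours, but
#' received at least one vasopressor administration before that. All three
#' clauses must hold for exclusion.
#'
#' @param raw A `raw_cohort` whose events include `vaso_admin`, `record_end`
#'   and `death_time` rows.
#' @return The filtered `raw_cohort`.
#' @export
apply_withdrawal_filter <- function(raw) {
  ev <- raw$events
  pts <- raw$outcomes$patient_id
  get_time <- function(type) {
    e <- ev[ev$event_type == type, ]
    e$event_time[match(pts, e$patient_id)]
  }
  rec_end <- get_time("record_end")
  death <- get_time("death_time")
  vaso <- ev[ev$event_type == "vaso_admin", ]
  withdrawn <- rep(FALSE, length(pts))
  cand <- which(!is.na(death) & !is.na(rec_end) & death - rec_end <= 24)
  for (i in cand) {
    vt <- vaso$event_time[vaso$patient_id == pts[i]]
    no_recent <- !any(vt > rec_end[i] - 24 & vt <= rec_end[i])
    earlier <- any(vt <= rec_end[i] - 24)
    withdrawn[i] <- no_recent && earlier
  }
  keep_patients(raw, pts[!withdrawn])
}

#' Bin observations into the onset-anchored analysis window
#'
#' Re-anchors each patient's clock to 24 h (configurable) before sepsis
#' onset, drops observations outside the window, and aggregates multiple
#' observations of a feature within a 4-hour bin by the feature's declared
#' rule (mean for levels, sum for flows). Vasopressor doses are averaged
#' (rates) and fluid volumes summed within a bin. Bins with no observation of
#' a feature remain missing for downstream imputation.
#'
#' @param raw A `raw_cohort` (after exclusions).
#' @param onsets Output of [identify_sepsis_onset()].
#' @param config A [preprocess_config()].
#' @return A wide trajectory data.frame (class `trajectory_table`):
#'   patient_id, bin_index, one column per feature, `vaso_dose`,
#'   `fluid_volume`, `died_90d`.
#' @export
bin_and_aggregate <- function(raw, onsets, config = preprocess_config()) {
  feats <- sort(unique(raw$observations$feature))
  known <- feats %in% names(config$aggregation)
  if (!all(known))
    stop_config("no aggregation rule declared for: ",
                paste(feats[!known], collapse = ", "))
  feature_names <- if (inherits(raw$config, "cohort_config"))
    raw$config$feature_names else feats

  width <- config$window_before_onset_h + config$window_after_onset_h
  nb <- width %/% config$bin_hours
  on <- onsets[!is.na(onsets$onset_h), ]
  w0 <- stats::setNames(on$onset_h - config$window_before_onset_h,
                        on$patient_id)

  obs <- raw$observations
  obs <- obs[obs$patient_id %in% on$patient_id, , drop = FALSE]
  rel <- obs$time_h - w0[as.character(obs$patient_id)]
  keep <- rel >= 0 & rel < width
  obs <- obs[keep, , drop = FALSE]
  bin <- as.integer(rel[keep] %/% config$bin_hours)

  ds <- raw$doses
  ds <- ds[ds$patient_id %in% on$patient_id, , drop = FALSE]
  drel <- ds$time_h - w0[as.character(ds$patient_id)]
  dkeep <- drel >= 0 & drel < width
  ds <- ds[dkeep, , drop = FALSE]
  dbin <- as.integer(drel[dkeep] %/% config$bin_hours)

  ## complete per-patient grid of consecutive bins up to the last observed bin
  pid_all <- c(obs$patient_id, ds$patient_id)
  bin_all <- c(bin, dbin)
  if (!length(pid_all)) {
    out <- data.frame(patient_id = integer(), bin_index = integer())
    for (f in feature_names) out[[f]] <- numeric()
    out$vaso_dose <- numeric(); out$fluid_volume <- numeric()
    out$died_90d <- logical()
    class(out) <- c("trajectory_table", "data.frame")
    attr(out, "feature_names") <- feature_names
    return(out)
  }
  maxbin <- tapply(bin_all, pid_all, max)
  pids <- as.numeric(names(maxbin))
  grid_pid <- rep(pids, maxbin + 1L)
  grid_bin <- unlist(lapply(maxbin, function(b) 0:b), use.names = FALSE)
  rowkey <- paste(grid_pid, grid_bin)

  ## aggregate observations per (patient, bin, feature)
  M <- matrix(NA_real_, length(grid_pid), length(feature_names),
              dimnames = list(NULL, feature_names))
  if (nrow(obs)) {
    gkey <- paste(obs$patient_id, bin, obs$feature, sep = "\r")
    sums <- rowsum(obs$value, gkey)
    cnts <- rowsum(rep(1, nrow(obs)), gkey)
    first <- !duplicated(gkey)
    fpid <- obs$patient_id[first]; fbin <- bin[first]
    ffeat <- obs$feature[first]
    ord <- match(rownames(sums), gkey[first])
    agg <- ifelse(config$aggregation[ffeat[ord]] == "sum",
                  sums[, 1], sums[, 1] / cnts[, 1])
    ri <- match(paste(fpid[ord], fbin[ord]), rowkey)
    ci <- match(ffeat[ord], feature_names)
    M[cbind(ri, ci)] <- agg
  }

  vaso <- numeric(length(grid_pid)); fluid <- numeric(length(grid_pid))
  if (nrow(ds)) {
    dkey <- paste(ds$patient_id, dbin)
    vs <- rowsum(ds$vaso_dose, dkey); vc <- rowsum(rep(1, nrow(ds)), dkey)
    fs <- rowsum(ds$fluid_volume, dkey)
    ri <- match(rownames(vs), rowkey)
    ok <- !is.na(ri)
    vaso[ri[ok]] <- (vs[, 1] / vc[, 1])[ok]   # mean rate within bin
    fluid[ri[ok]] <- fs[ok, 1]                # summed volume within bin
  }

  died <- raw$outcomes$died_90d[match(grid_pid, raw$outcomes$patient_id)]
  out <- data.frame(patient_id = grid_pid, bin_index = grid_bin,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(M, check.names = FALSE))
  out$vaso_dose <- vaso
  out$fluid_volume <- fluid
  out$died_90d <- died
  out <- out[order(out$patient_id, out$bin_index), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$bin_index < nb))
  class(out) <- c("trajectory_table", "data.frame")
  attr(out, "feature_names") <- feature_names
  out
}

traj_features <- function(traj) {
  attr(traj, "feature_names") %||%
    setdiff(names(traj), c("patient_id", "bin_index", "vaso_dose",
                           "fluid_volume", "died_90d", "split"))
}

#' Clamp feature values to plausible physiological bounds
#'
#' @param traj A `trajectory_table`.
#' @param config A [preprocess_config()]; only features listed in
#'   `config$cap_bounds` are clamped.
#' @return The capped `trajectory_table`.
#' @export
cap_values <- function(traj, config = preprocess_config()) {
  for (f in intersect(traj_features(traj), names(config$cap_bounds))) {
    b <- config$cap_bounds[[f]]
    traj[[f]] <- pmin(pmax(traj[[f]], b[1]), b[2])
  }
  traj
}

#' Assign a deterministic patient-level train/test split
#'
#' Patients (never individual bins) are assigned to the training split with
#' probability `train_fraction`, rounded to the nearest patient count, under
#' `split_seed`.
#'
#' @param traj A `trajectory_table`.
#' @param config A [preprocess_config()].
#' @return The `trajectory_table` with a `split` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(traj, config = preprocess_config()) {
  pts <- unique(traj$patient_id)
  if (length(pts) < 5L) stop_config("need at least 5 patients to split")
  n_train <- round(config$train_fraction * length(pts))
  train <- with_seed(config$split_seed, sample(pts, n_train))
  traj$split <- ifelse(traj$patient_id %in% train, "train", "test")
  traj
}

#' Impute missing feature values by zero-order hold
#'
#' Per patient and feature, the last observed value is carried forward; a
#' leading gap is back-filled from the first observation; a feature never
#' observed for a patient falls back to the training-cohort median (computed
#' from observed training values, so no test-set leakage). The result has no
#' missing feature values.
#'
#' @param traj A `trajectory_table`, ideally already split so training
#'   medians are available.
#' @param medians Optional named vector of fallback medians (e.g. from a
#'   previously imputed training table); computed from the data when `NULL`.
#' @return The imputed `trajectory_table`, with the medians used stored in
#'   `attr(, "medians")`.
#' @export
impute_trajectories <- function(traj, medians = NULL) {
  traj <- traj[order(traj$patient_id, traj$bin_index), , drop = FALSE]
  feats <- traj_features(traj)
  ref_rows <- if (!is.null(traj$split)) traj$split == "train"
              else rep(TRUE, nrow(traj))
  pid <- traj$patient_id
  starts <- which(!duplicated(pid))
  pstart <- rep(starts, diff(c(starts, nrow(traj) + 1L)))
  pend <- rep(c(starts[-1L] - 1L, nrow(traj)),
              diff(c(starts, nrow(traj) + 1L)))
  med <- stats::setNames(numeric(length(feats)), feats)
  n <- nrow(traj)
  i <- seq_len(n)
  for (f in feats) {
    x <- traj[[f]]
    if (is.null(medians)) {
      med[f] <- stats::median(x[ref_rows], na.rm = TRUE)
    } else {
      if (!f %in% names(medians))
        stop_config("no fallback median supplied for feature ", f)
      med[f] <- medians[[f]]
    }
    if (is.na(med[f]))
      stop_config("feature observed nowhere in the (training) cohort: ", f)
    o <- !is.na(x)
    if (any(is.na(x))) {
      last <- cummax(ifelse(o, i, 0L))                       # forward fill
      nxt_r <- cummax(ifelse(rev(o), i, 0L))                 # backward fill
      nxt <- (n + 1L) - rev(nxt_r)
      y <- x
      use_f <- is.na(x) & last >= pstart
      y[use_f] <- x[last[use_f]]
      use_b <- is.na(y) & nxt <= pend
      y[use_b] <- x[nxt[use_b]]
      y[is.na(y)] <- med[f]
      traj[[f]] <- y
    }
  }
  rownames(traj) <- NULL
  attr(traj, "medians") <- med
  class(traj) <- c("trajectory_table", "data.frame")
  attr(traj, "feature_names") <- feats
  traj
}

#' Run the full preprocessing pipeline on a raw cohort
#'
#' Sepsis-onset identification, exclusions, withdrawal filter, onset-anchored
#' 4-hour binning with type-aware aggregation, value capping, patient-level
#' train/test split, and zero-order-hold imputation (training medians as the
#' fallback).
#'
#' @param raw A `raw_cohort`.
#' @param config A [preprocess_config()].
#' @return An imputed, split `trajectory_table`.
#' @export
preprocess_cohort <- function(raw, config = preprocess_config()) {
  onsets <- identify_sepsis_onset(raw$events)
  raw <- apply_exclusions(raw, onsets)
  raw <- apply_withdrawal_filter(raw)
  traj <- bin_and_aggregate(raw, onsets, config)
  traj <- cap_values(traj, config)
  traj <- split_train_test(traj, config)
  impute_trajectories(traj)
}
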