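#' Configuration for the synthetic septic cohort generator
#'
#' Describes the statistical shape of a simulated cohort: cohort size, the 48
#' modelled features (which must contain the six cardiorespiratory and the six
#' reference features), per-bin laboratory missingness, zero-inflation of the
#' two treatment doses, the strength of the survival benefit conferred by
#' latent-appropriate dosing, and the per-bin death hazard from the worst
#' severity level.
#'
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed; the generator is deterministic given
#'   `(config, truth, seed)`.
#' @param n_bins_max Maximum number of 4-hour bins per patient (default 18,
#'   i.e. 24 h before to 48 h after sepsis onset).
#' @param feature_names The 48 feature names (see [default_feature_names()]).
#' @param lab_missing_prob Probability that a laboratory feature is missing in
#'   a given bin.
#' @param dose_zero_prob_vaso,dose_zero_prob_fluid Zero-inflation
#'   probabilities of the marginal vasopressor / IV-fluid dose laws.
#' @param treatment_effect Nonnegative real; strength of the severity
#'   improvement when the administered action equals the latent-optimal
#'   action. The per-bin improvement probability is
#'   `treatment_effect / (1 + treatment_effect)`.
#' @param mortality_base Per-bin death probability from the worst severity
#'   level.
#' @param behavior Data-generating (behaviour) policy: `"clinician"` takes
#'   the latent-optimal action with probability `p_optimal` and otherwise
#'   explores uniformly over the 25-action grid (guaranteeing the overlap
#'   off-policy evaluation needs); `"optimal"` always doses optimally;
#'   `"never_treat"` never doses; `"marginal"` doses from the zero-inflated
#'   lognormal law with the configured zero probabilities.
#' @param p_optimal Probability mass of the optimal action under the
#'   `"clinician"` behaviour.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          seed = 1L,
                          n_bins_max = 18L,
                          feature_names = default_feature_names(),
                          lab_missing_prob = 0.6,
                          dose_zero_prob_vaso = 0.85,
                          dose_zero_prob_fluid = 0.3,
                          treatment_effect = 1,
                          mortality_base = 0.2,
                          behavior = c("clinician", "optimal", "never_treat",
                                       "marginal"),
                          p_optimal = 0.5) {
  behavior <- match.arg(behavior)
  if (length(feature_names) != 48L || anyDuplicated(feature_names))
    stop_config("feature_names must hold exactly 48 unique names")
  if (!all(cardio_features() %in% feature_names))
    stop_config("feature_names must include the six cardiorespiratory features")
  if (!all(baseline_features() %in% feature_names))
    stop_config("feature_names must include the six reference features")
  probs <- c(lab_missing_prob, dose_zero_prob_vaso, dose_zero_prob_fluid,
             mortality_base, p_optimal)
  if (any(probs < 0 | probs > 1))
    stop_config("all probabilities must lie in [0, 1]")
  if (n_bins_max < 2L) stop_config("n_bins_max must be at least 2")
  if (treatment_effect < 0) stop_config("treatment_effect must be nonnegative")
  if (n_patients < 0) stop_config("n_patients must be nonnegative")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 n_bins_max = as.integer(n_bins_max),
                 feature_names = feature_names,
                 lab_missing_prob = lab_missing_prob,
                 dose_zero_prob_vaso = dose_zero_prob_vaso,
                 dose_zero_prob_fluid = dose_zero_prob_fluid,
                 treatment_effect = treatment_effect,
                 mortality_base = mortality_base,
                 behavior = behavior, p_optimal = p_optimal),
            class = "cohort_config")
}

#' Latent ground truth of the synthetic cohort
#'
#' The simulator drives each patient through a 5-level latent severity chain
#' with an absorbing recovery exit (from the mildest level) and an absorbing
#' death exit (from the worst level). Observed features are noisy emissions of
#' the latent level: each informative feature carries a linear severity slope,
#' all features share a small set of latent noise factors (giving the feature
#' covariance a low-rank-plus-diagonal structure), and an idiosyncratic noise
#' term. The mapping from latent level to the treatment action that promotes
#' improvement is the known ground truth used by policy-recovery checks.
#'
#' @param n_latent_states Number of severity levels (default 5; level 1 is the
#'   mildest, level `n` the most severe).
#' @param latent_transition_base Row-stochastic matrix of untreated severity
#'   dynamics; default worsens with probability 0.3, holds 0.5, improves 0.2
#'   (boundary mass folded into "hold").
#' @param optimal_action_by_latent Integer vector of 0-based action ids (one
#'   per severity level); the default escalates both treatments with severity
#'   (`0, 6, 12, 18, 24`).
#' @param informative_features Feature names whose emissions depend on the
#'   latent severity; default: all dynamic features (static demographics
#'   excluded).
#' @param feature_names The 48 modelled feature names.
#' @param recovery_prob Per-bin probability of the absorbing recovery
#'   (discharge) exit from the mildest level. The default keeps early
#'   discharge uncommon: septic ICU stays usually span the whole 72-hour
#'   analysis window, and most survival is resolved by the severity-linked
#'   residual mortality at the window end.
#' @param overtreatment_harm Per-bin probability that severity worsens by one
#'   level when either administered treatment exceeds its latent-optimal
#'   dose bin: excessive fluid loading and unneeded vasopressor exposure are
#'   harmful, not neutral.
#' @param residual_mortality Probability of death within 90 days for a
#'   patient still in the ICU at the end of the observation window, as a
#'   function of the final severity level; surviving the window is not a
#'   cure, and 90-day mortality rises steeply with discharge-time severity.
#' @param d0_latent Initial severity distribution.
#' @param slope_range Range of the per-severity-level mean shift of an
#'   informative feature, in units of its emission scale. The default keeps
#'   the five severity levels resolvable by a k-means state model of 50-750
#'   clusters — an identifiability requirement for ground-truth policy
#'   recovery, since the behaviour policy acts on the true severity and any
#'   within-cluster severity mixture confounds the apparent action effects.
#' @param n_noise_factors,factor_loading Number of shared latent noise factors
#'   and the loading of each feature on its two factors.
#' @param emission_seed Seed fixing the (deterministic) emission slopes and
#'   factor loadings.
#' @return An object of class `latent_ground_truth`.
#' @export
latent_ground_truth <- function(n_latent_states = 5L,
                                latent_transition_base = NULL,
                                optimal_action_by_latent = NULL,
                                informative_features = NULL,
                                feature_names = default_feature_names(),
                                recovery_prob = 0.35,
                                overtreatment_harm = 0.25,
                                residual_mortality = NULL,
                                d0_latent = NULL,
                                slope_range = c(1.5, 3.5),
                                n_noise_factors = 12L,
                                factor_loading = 0.6,
                                emission_seed = 193L) {
  nz <- as.integer(n_latent_states)
  if (nz < 2L) stop_config("need at least 2 latent severity levels")
  p <- length(feature_names)
  if (is.null(latent_transition_base)) {
    latent_transition_base <- matrix(0, nz, nz)
    for (z in seq_len(nz)) {
      up <- if (z < nz) 0.3 else 0
      down <- if (z > 1L) 0.2 else 0
      latent_transition_base[z, z] <- 1 - up - down
      if (z < nz) latent_transition_base[z, z + 1L] <- up
      if (z > 1L) latent_transition_base[z, z - 1L] <- down
    }
  }
  if (!all(abs(rowSums(latent_transition_base) - 1) < 1e-12))
    stop_config("latent_transition_base rows must sum to 1")
  if (is.null(optimal_action_by_latent)) {
    b <- round((seq_len(nz) - 1) / (nz - 1) * 4)
    optimal_action_by_latent <- as.integer(5L * b + b)
  }
  if (length(optimal_action_by_latent) != nz)
    stop_config("optimal_action_by_latent must cover every latent state")
  if (any(optimal_action_by_latent < 0L | optimal_action_by_latent > 24L))
    stop_config("optimal actions must be ids in [0, 25)")
  if (is.null(d0_latent)) {
    d0_latent <- if (nz == 5L) c(0.10, 0.25, 0.30, 0.22, 0.13)
                 else rep(1 / nz, nz)
  }
  d0_latent <- d0_latent / sum(d0_latent)
  if (is.null(residual_mortality)) {
    residual_mortality <- if (nz == 5L) c(0.02, 0.05, 0.12, 0.30, 0.60)
                          else stats::plogis(3 * (seq_len(nz) - nz + 0.5))
  }
  if (length(residual_mortality) != nz ||
      any(residual_mortality < 0 | residual_mortality > 1))
    stop_config("residual_mortality must be one probability per latent state")

  cat <- feature_catalog()
  cat <- cat[match(feature_names, cat$name), , drop = FALSE]
  if (anyNA(cat$name))
    stop_config("feature_names must come from feature_catalog()")
  if (is.null(informative_features))
    informative_features <- cat$name[!cat$static & cat$name != "rrt"]

  mid <- (nz + 1) / 2
  slopes <- stats::setNames(numeric(p), feature_names)
  loadings <- matrix(0, p, n_noise_factors,
                     dimnames = list(feature_names, NULL))
  with_seed(emission_seed, {
    inf <- feature_names %in% informative_features
    slopes[inf] <- stats::runif(sum(inf), slope_range[1], slope_range[2])
    for (j in seq_len(p)) {
      loadings[j, sample.int(n_noise_factors, 2L)] <- factor_loading
    }
  })
  emission_means <- outer(seq_len(nz) - mid, slopes)  # nz x p
  emission_sds <- matrix(0.5, nz, p, dimnames = list(NULL, feature_names))

  vaso_meanlog <- log(0.1); vaso_sdlog <- 0.9
  fluid_meanlog <- log(250); fluid_sdlog <- 0.8
  structure(list(
    n_latent_states = nz,
    latent_transition_base = latent_transition_base,
    optimal_action_by_latent = optimal_action_by_latent,
    informative_features = informative_features,
    feature_names = feature_names,
    recovery_prob = recovery_prob,
    overtreatment_harm = overtreatment_harm,
    residual_mortality = residual_mortality,
    d0_latent = d0_latent,
    slopes = slopes,
    noise_loadings = loadings,
    emission_means = emission_means,
    emission_sds = emission_sds,
    vaso_meanlog = vaso_meanlog, vaso_sdlog = vaso_sdlog,
    fluid_meanlog = fluid_meanlog, fluid_sdlog = fluid_sdlog,
    vaso_edges = stats::qlnorm(c(0.25, 0.5, 0.75), vaso_meanlog, vaso_sdlog),
    fluid_edges = stats::qlnorm(c(0.25, 0.5, 0.75), fluid_meanlog, fluid_sdlog)
  ), class = "latent_ground_truth")
}

## dose bin under known quartile edges: 0 -> 0, (0,q25] -> 1, ... , >q75 -> 4
dose_bin_known <- function(x, edges) {
  b <- findInterval(x, edges, left.open = TRUE) + 1L
  b[x == 0] <- 0L
  b
}

## inverse-CDF draw of a dose inside quartile bin b (1..4); bin 0 -> 0
dose_from_bin <- function(b, meanlog, sdlog) {
  u <- stats::runif(length(b), pmax(b - 1, 0) / 4, pmax(b, 1) / 4)
  d <- stats::qlnorm(u, meanlog, sdlog)
  d[b == 0L] <- 0
  d
}


#' Generate a synthetic septic ICU cohort
#'
#' Simulates `config$n_patients` patients through the latent severity process
#' of `truth` under the configured behaviour policy, and emits the raw tables
#' a real extraction would provide: a long observations table (with
#' laboratory sparsity), a per-bin dose table, a per-patient outcomes table,
#' an events table (antibiotics, microbiological sampling, vasopressor
#' administrations, record end, death time) driving the cohort-definition
#' rules, and — because the cohort is synthetic — the latent ground truth per
#' bin for validation.
#'
#' Recording starts 24 h before sepsis onset, so bin 0 of the recording clock
#' coincides with bin 0 of the onset-anchored analysis window.
#'
#' @param config A [cohort_config()].
#' @param truth A [latent_ground_truth()]; its feature set must match
#'   `config$feature_names`.
#' @return An object of class `raw_cohort`: list with elements
#'   `observations` (patient_id, bin_index, time_h, feature, value),
#'   `doses` (patient_id, bin_index, time_h, vaso_dose, fluid_volume),
#'   `outcomes` (patient_id, died_90d, outcome_documented, fluids_documented,
#'   age), `events` (patient_id, event_time, event_type) and `latents`
#'   (patient_id, bin_index, latent, optimal_action, action).
#' @export
generate_cohort <- function(config, truth = latent_ground_truth(
                              feature_names = config$feature_names)) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(truth, "latent_ground_truth"))
  if (!identical(truth$feature_names, config$feature_names))
    stop_config("truth and config feature sets are inconsistent")
  p <- length(config$feature_names)
  if (ncol(truth$emission_means) != p ||
      nrow(truth$emission_means) != truth$n_latent_states)
    stop_config("emission matrix dimensions inconsistent with config")

  ## The exploration branch's nonzero bin weights start uniform and are
  ## recalibrated on a light pre-pass so that the cohort's pooled nonzero
  ## dose quartiles coincide with the generator's action-label edges (the
  ## optimal-dosing branch concentrates mass on the severity-matched bins
  ## and would otherwise shift the fitted quartile grid off the ground
  ## truth's action labels).
  q_vaso <- q_fluid <- rep(0.25, 4)
  if (config$behavior == "clinician" && config$n_patients > 0L) {
    tl <- cohort_pass(config, truth, derive_seed(config$seed, 7L),
                      q_vaso, q_fluid, full = FALSE)
    q_vaso <- compensate_bins(tl$opt_vaso, tl$expl_vaso)
    q_fluid <- compensate_bins(tl$opt_fluid, tl$expl_fluid)
  }
  sim <- cohort_pass(config, truth, config$seed, q_vaso, q_fluid,
                     full = TRUE)

  n <- config$n_patients
  cat <- feature_catalog()
  cat <- cat[match(config$feature_names, cat$name), , drop = FALSE]
  observations <- do.call(rbind, sim$obs_pieces)
  doses <- do.call(rbind, sim$dose_pieces)
  latents <- do.call(rbind, sim$lat_pieces)
  if (is.null(observations)) {
    observations <- data.frame(patient_id = integer(), bin_index = integer(),
                               time_h = numeric(), feature = character(),
                               value = numeric())
    doses <- data.frame(patient_id = integer(), bin_index = integer(),
                        time_h = numeric(), vaso_dose = numeric(),
                        fluid_volume = numeric())
    latents <- data.frame(patient_id = integer(), bin_index = integer(),
                          latent = integer(), optimal_action = integer(),
                          action = integer())
  }
  o <- order(observations$patient_id, observations$bin_index,
             match(observations$feature, cat$name))
  observations <- observations[o, , drop = FALSE]
  rownames(observations) <- NULL
  doses <- doses[order(doses$patient_id, doses$bin_index), , drop = FALSE]
  rownames(doses) <- NULL
  latents <- latents[order(latents$patient_id, latents$bin_index), ,
                     drop = FALSE]
  rownames(latents) <- NULL

  if (n > 0L) {
    outcomes <- data.frame(patient_id = seq_len(n), died_90d = sim$died,
                           outcome_documented = sim$out_doc,
                           fluids_documented = sim$flu_doc, age = sim$age)
    record_end <- 4 * (sim$last_bin + 1L)
    ev <- list(
      data.frame(patient_id = seq_len(n), event_time = 24,
                 event_type = "micro_sample", stringsAsFactors = FALSE),
      data.frame(patient_id = seq_len(n), event_time = 24 + sim$ab_delay,
                 event_type = "antibiotic", stringsAsFactors = FALSE),
      data.frame(patient_id = seq_len(n), event_time = record_end,
                 event_type = "record_end", stringsAsFactors = FALSE))
    va <- doses[doses$vaso_dose > 0, c("patient_id", "time_h")]
    if (nrow(va))
      ev[[length(ev) + 1L]] <- data.frame(patient_id = va$patient_id,
                                          event_time = va$time_h,
                                          event_type = "vaso_admin",
                                          stringsAsFactors = FALSE)
    if (any(sim$died)) {
      ## in-window deaths end the recording; residual 90-day deaths occur
      ## well after discharge
      dt <- ifelse(sim$died_in_window, record_end,
                   record_end + sim$resid_delay)
      ev[[length(ev) + 1L]] <- data.frame(patient_id = which(sim$died),
                                          event_time = dt[sim$died],
                                          event_type = "death_time",
                                          stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, ev)
    events <- events[order(events$patient_id, events$event_time), ,
                     drop = FALSE]
    rownames(events) <- NULL
  } else {
    outcomes <- data.frame(patient_id = integer(), died_90d = logical(),
                           outcome_documented = logical(),
                           fluids_documented = logical(), age = numeric())
    events <- data.frame(patient_id = integer(), event_time = numeric(),
                         event_type = character())
  }

  structure(list(observations = observations, doses = doses,
                 outcomes = outcomes, events = events, latents = latents,
                 config = config, truth = truth),
            class = "raw_cohort")
}

## Reweight the exploration branch's nonzero bin probabilities of one
## treatment so the pooled nonzero dose distribution has ~1/4 of its mass in
## each quartile segment of the generating lognormal (making the
## quartile-fitted action grid reproduce the generator's action labels).
compensate_bins <- function(opt_counts, n_explore) {
  if (n_explore <= 0) return(rep(0.25, 4))
  total <- sum(opt_counts) + n_explore
  q <- (total / 4 - opt_counts) / n_explore
  q <- pmax(q, 0)
  q / sum(q)
}

## One simulation pass over the cohort: latent chain, behaviour dosing in
## dose-bin space, feature emissions, and exit bookkeeping. With
## full = FALSE only the dose-bin tallies for compensate_bins are returned.
cohort_pass <- function(config, truth, seed, q_vaso, q_fluid, full = TRUE) {
  n <- config$n_patients
  cat <- feature_catalog()
  cat <- cat[match(config$feature_names, cat$name), , drop = FALSE]
  p <- nrow(cat)
  is_lab <- cat$lab
  nz <- truth$n_latent_states
  nf <- ncol(truth$noise_loadings)
  p_eff <- config$treatment_effect / (1 + config$treatment_effect)
  cum_qv <- cumsum(q_vaso); cum_qf <- cumsum(q_fluid)

  obs_pieces <- list(); dose_pieces <- list(); lat_pieces <- list()
  opt_vaso <- opt_fluid <- rep(0, 4)
  expl_vaso <- expl_fluid <- 0

  with_seed(seed, {
    age <- stats::runif(n, 16, 90)
    weight <- 80 + 18 * stats::rnorm(n)
    gender <- stats::rbinom(n, 1L, 0.5)
    readm <- stats::rbinom(n, 1L, 0.3)
    out_doc <- stats::rbinom(n, 1L, 0.98) == 1L
    flu_doc <- stats::rbinom(n, 1L, 0.97) == 1L
    ab_delay <- stats::runif(n, 1, 48)
    z <- sample.int(nz, n, replace = TRUE, prob = truth$d0_latent)
    active <- rep(TRUE, n)
    died <- rep(FALSE, n)
    last_bin <- rep(NA_integer_, n)
    static_vals <- cbind(age = age, weight = weight,
                         gender = gender, readmission = readm)
    ## persistent patient-level factor scores: baselines differ across
    ## patients and persist across bins, so successive observations of one
    ## patient stay in the same region of feature space
    pat_fac <- matrix(stats::rnorm(n * nf), n, nf)
    cum_trans <- t(apply(truth$latent_transition_base, 1L, cumsum))

    for (t in 0:(config$n_bins_max - 1L)) {
      ids <- which(active)
      m <- length(ids)
      if (m == 0L) break
      zz <- z[ids]
      a_star <- truth$optimal_action_by_latent[zz]

      ## behaviour in dose-bin space: the clinician takes the latent-optimal
      ## action with probability p_optimal and otherwise explores uniformly
      ## over the 25-action grid (guaranteeing overlap for off-policy
      ## evaluation); "marginal" doses from the zero-inflated lognormal law
      opt_branch <- switch(config$behavior,
        clinician   = stats::runif(m) < config$p_optimal,
        optimal     = rep(TRUE, m),
        never_treat = rep(FALSE, m),
        marginal    = rep(FALSE, m))
      vb <- fb <- integer(m)
      vb[opt_branch] <- a_star[opt_branch] %/% 5L
      fb[opt_branch] <- a_star[opt_branch] %% 5L
      mg <- which(!opt_branch)
      if (length(mg) && config$behavior == "clinician") {
        ## each treatment: null bin w.p. 1/5, else a nonzero bin from the
        ## (near-uniform) calibrated weights
        kk <- length(mg)
        v0 <- stats::runif(kk) < 0.2
        f0 <- stats::runif(kk) < 0.2
        vbm <- findInterval(stats::runif(kk), cum_qv, left.open = TRUE) + 1L
        fbm <- findInterval(stats::runif(kk), cum_qf, left.open = TRUE) + 1L
        vbm[v0] <- 0L; fbm[f0] <- 0L
        vb[mg] <- vbm; fb[mg] <- fbm
      } else if (length(mg) && config$behavior == "marginal") {
        kk <- length(mg)
        v0 <- stats::runif(kk) < config$dose_zero_prob_vaso
        f0 <- stats::runif(kk) < config$dose_zero_prob_fluid
        vbm <- sample(1:4, kk, replace = TRUE)
        fbm <- sample(1:4, kk, replace = TRUE)
        vbm[v0] <- 0L; fbm[f0] <- 0L
        vb[mg] <- vbm; fb[mg] <- fbm
      }
      act <- 5L * vb + fb

      if (!full) {
        ov <- vb[opt_branch]; of <- fb[opt_branch]
        opt_vaso <- opt_vaso + tabulate(ov[ov > 0L], nbins = 4L)
        opt_fluid <- opt_fluid + tabulate(of[of > 0L], nbins = 4L)
        expl_vaso <- expl_vaso + sum(vb[mg] > 0L)
        expl_fluid <- expl_fluid + sum(fb[mg] > 0L)
      } else {
        vaso <- dose_from_bin(vb, truth$vaso_meanlog, truth$vaso_sdlog)
        fluid <- dose_from_bin(fb, truth$fluid_meanlog, truth$fluid_sdlog)

        ## feature emissions (standardized scale) mapped to native units
        X <- truth$emission_means[zz, , drop = FALSE] +
          pat_fac[ids, , drop = FALSE] %*% t(truth$noise_loadings) +
          matrix(stats::rnorm(m * p, sd = 0.5), m, p)
        vals <- sweep(sweep(X, 2L, cat$scale, `*`), 2L, cat$base, `+`)
        colnames(vals) <- cat$name
        mv_slope <- truth$slopes["mech_vent"]
        pr_mv <- if ("mech_vent" %in% truth$informative_features)
          stats::plogis(2 * mv_slope * (zz - (nz + 1) / 2)) else rep(0.3, m)
        u_bin <- stats::runif(m); u_rrt <- stats::runif(m)
        if ("mech_vent" %in% cat$name)
          vals[, "mech_vent"] <- as.numeric(u_bin < pr_mv)
        if ("rrt" %in% cat$name)
          vals[, "rrt"] <- as.numeric(u_rrt < 0.08)
        for (sn in colnames(static_vals))
          if (sn %in% cat$name) vals[, sn] <- static_vals[ids, sn]

        keep <- matrix(TRUE, m, p)
        nlab <- sum(is_lab)
        if (nlab > 0L)
          keep[, is_lab] <- matrix(stats::runif(m * nlab), m, nlab) >=
            config$lab_missing_prob
        w <- which(keep)
        ri <- ((w - 1L) %% m) + 1L
        ci <- ((w - 1L) %/% m) + 1L
        obs_pieces[[length(obs_pieces) + 1L]] <- data.frame(
          patient_id = ids[ri], bin_index = t, time_h = 4 * t + 2,
          feature = cat$name[ci], value = vals[w],
          stringsAsFactors = FALSE)
        dose_pieces[[length(dose_pieces) + 1L]] <- data.frame(
          patient_id = ids, bin_index = t, time_h = 4 * t + 2,
          vaso_dose = vaso, fluid_volume = fluid)
        lat_pieces[[length(lat_pieces) + 1L]] <- data.frame(
          patient_id = ids, bin_index = t, latent = zz,
          optimal_action = a_star, action = act)
      }

      ## latent transition: matched treatment promotes improvement
      matched <- act == a_star
      u_imp <- stats::runif(m)
      u_tr <- stats::runif(m)
      z2 <- integer(m)
      for (lz in seq_len(nz)) {
        sel <- zz == lz
        if (any(sel))
          z2[sel] <- findInterval(u_tr[sel], cum_trans[lz, ],
                                  left.open = TRUE) + 1L
      }
      improve <- matched & u_imp < p_eff
      z2[improve] <- pmax(zz[improve] - 1L, 1L)
      ## overtreatment toxicity: dosing above the optimal bin can worsen
      overshoot <- !matched & (vb > a_star %/% 5L | fb > a_star %% 5L)
      u_harm <- stats::runif(m)
      harm <- overshoot & u_harm < truth$overtreatment_harm
      z2[harm] <- pmin(zz[harm] + 1L, nz)
      u_die <- stats::runif(m); u_rec <- stats::runif(m)
      die <- z2 == nz & u_die < config$mortality_base
      rec <- !die & z2 == 1L & u_rec < truth$recovery_prob
      exit <- die | rec
      died[ids[die]] <- TRUE
      last_bin[ids[exit]] <- t
      active[ids[exit]] <- FALSE
      z[ids] <- z2
    }
    last_bin[is.na(last_bin)] <- config$n_bins_max - 1L
    ## patients still in the ICU at window end: residual 90-day mortality
    ## driven by their final severity (window survival is not a cure)
    died_in_window <- died
    if (any(active)) {
      u_res <- stats::runif(sum(active))
      died[active] <- u_res < truth$residual_mortality[z[active]]
    }
    resid_delay <- stats::runif(n, 48, 720)
  })

  list(obs_pieces = obs_pieces, dose_pieces = dose_pieces,
       lat_pieces = lat_pieces, died = died,
       died_in_window = died_in_window, resid_delay = resid_delay,
       out_doc = out_doc, flu_doc = flu_doc, age = age, ab_delay = ab_delay,
       last_bin = last_bin, opt_vaso = opt_vaso, opt_fluid = opt_fluid,
       expl_vaso = expl_vaso, expl_fluid = expl_fluid)
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat("Synthetic septic cohort:", nrow(x$outcomes), "patients,",
      nrow(x$doses), "patient-bins,", nrow(x$observations),
      "observations\n")
  if (nrow(x$outcomes))
    cat(sprintf("90-day mortality: %.1f%%\n", 100 * mean(x$outcomes$died_90d)))
  invisible(x)
}

#' Generate antibiotic / microbiological sampling event pairs
#'
#' Emits one antibiotic--sampling pair per patient covering the three cases of
#' the sepsis-onset rule in requested proportions: (1) sampling first with the
#' antibiotic within 72 h (qualifies), (2) antibiotic first with the sampling
#' within 24 h (qualifies), (3) antibiotic more than 72 h after the sampling
#' (does not qualify).
#'
#' @param n_patients Number of patients.
#' @param proportions Length-3 nonnegative weights of the three cases.
#' @param seed Integer seed.
#' @return Events data.frame (patient_id, event_time, event_type) with the
#'   simulated case per patient in `attr(, "case")`.
#' @export
generate_events_for_onset <- function(n_patients, proportions = c(0.4, 0.4, 0.2),
                                      seed = 1L) {
  stopifnot(length(proportions) == 3L, all(proportions >= 0),
            sum(proportions) > 0)
  if (n_patients == 0L) {
    out <- data.frame(patient_id = integer(), event_time = numeric(),
                      event_type = character())
    attr(out, "case") <- integer()
    return(out)
  }
  with_seed(seed, {
    case <- sample.int(3L, n_patients, replace = TRUE,
                       prob = proportions / sum(proportions))
    base <- stats::runif(n_patients, 0, 24)
    t_micro <- t_anti <- numeric(n_patients)
    i1 <- case == 1L; i2 <- case == 2L; i3 <- case == 3L
    t_micro[i1] <- base[i1]
    t_anti[i1] <- base[i1] + stats::runif(sum(i1), 0, 72)
    t_anti[i2] <- base[i2]
    t_micro[i2] <- base[i2] + stats::runif(sum(i2), 0.5, 24)
    t_micro[i3] <- base[i3]
    t_anti[i3] <- base[i3] + 72 + stats::runif(sum(i3), 1, 48)
  })
  out <- rbind(
    data.frame(patient_id = seq_len(n_patients), event_time = t_micro,
               event_type = "micro_sample", stringsAsFactors = FALSE),
    data.frame(patient_id = seq_len(n_patients), event_time = t_anti,
               event_type = "antibiotic", stringsAsFactors = FALSE))
  out <- out[order(out$patient_id, out$event_time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "case") <- case
  out
}
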