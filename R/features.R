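#' Catalogue of the 48 modelled clinical variables
#'
#' One row per feature used to describe the patient state: vital signs,
#' ventilation and demographics (22 non-laboratory features) plus 26
#' laboratory values. `base` and `scale` are the location/scale used by the
#' synthetic generator to place values on a plausible physiological range;
#' `agg` is the within-bin aggregation rule (flow-like quantities are summed,
#' level-like quantities averaged); `lab` flags features that arrive with
#' laboratory latency and sparsity; `binary` and `static` flag 0/1 features
#' and per-patient constants.
#'
#' @return A data.frame with columns `name`, `lab`, `binary`, `static`,
#'   `base`, `scale`, `agg`.
#' @export
feature_catalog <- function() {
  row <- function(name, lab, binary, static, base, scale, agg)
    data.frame(name = name, lab = lab, binary = binary, static = static,
               base = base, scale = scale, agg = agg,
               stringsAsFactors = FALSE)
  rbind(
    ## non-laboratory (22)
    row("heart_rate",         FALSE, FALSE, FALSE,  85,   15, "mean"),
    row("systolic_bp",        FALSE, FALSE, FALSE, 115,   20, "mean"),
    row("diastolic_bp",       FALSE, FALSE, FALSE,  60,   12, "mean"),
    row("mean_bp",            FALSE, FALSE, FALSE,  78,   14, "mean"),
    row("shock_index",        FALSE, FALSE, FALSE, 0.75, 0.18, "mean"),
    row("spo2",               FALSE, FALSE, FALSE,  96,    3, "mean"),
    row("resp_rate",          FALSE, FALSE, FALSE,  19,    5, "mean"),
    row("body_temperature",   FALSE, FALSE, FALSE,  37,  0.8, "mean"),
    row("mech_vent",          FALSE, TRUE,  FALSE,   0,    1, "mean"),
    row("gcs",                FALSE, FALSE, FALSE,  12,    3, "mean"),
    row("gender",             FALSE, TRUE,  TRUE,    0,    1, "mean"),
    row("age",                FALSE, FALSE, TRUE,   62,   16, "mean"),
    row("weight",             FALSE, FALSE, TRUE,   80,   18, "mean"),
    row("readmission",        FALSE, TRUE,  TRUE,    0,    1, "mean"),
    row("elixhauser",         FALSE, FALSE, FALSE,   3,    2, "mean"),
    row("sofa",               FALSE, FALSE, FALSE,   6,    3, "mean"),
    row("urine_output",       FALSE, FALSE, FALSE, 120,   60, "sum"),
    row("total_fluid_input",  FALSE, FALSE, FALSE, 300,  150, "sum"),
    row("fluid_balance",      FALSE, FALSE, FALSE, 150,  180, "sum"),
    row("cumulative_balance", FALSE, FALSE, FALSE, 1500, 900, "mean"),
    row("fio2",               FALSE, FALSE, FALSE, 0.5, 0.15, "mean"),
    row("rrt",                FALSE, TRUE,  FALSE,   0,    1, "mean"),
    ## laboratory (26)
    row("chloride",           TRUE, FALSE, FALSE, 102,    5, "mean"),
    row("potassium",          TRUE, FALSE, FALSE, 4.2,  0.5, "mean"),
    row("sodium",             TRUE, FALSE, FALSE, 139,    4, "mean"),
    row("glucose",            TRUE, FALSE, FALSE, 140,   40, "mean"),
    row("bun",                TRUE, FALSE, FALSE,  25,   12, "mean"),
    row("creatinine",         TRUE, FALSE, FALSE, 1.3,  0.8, "mean"),
    row("magnesium",          TRUE, FALSE, FALSE,   2,  0.3, "mean"),
    row("calcium",            TRUE, FALSE, FALSE, 8.5,  0.7, "mean"),
    row("ionized_calcium",    TRUE, FALSE, FALSE, 1.1,  0.1, "mean"),
    row("co2",                TRUE, FALSE, FALSE,  24,    4, "mean"),
    row("sgot",               TRUE, FALSE, FALSE,  60,   40, "mean"),
    row("sgpt",               TRUE, FALSE, FALSE,  55,   35, "mean"),
    row("total_bilirubin",    TRUE, FALSE, FALSE, 1.2,    1, "mean"),
    row("albumin",            TRUE, FALSE, FALSE,   3,  0.5, "mean"),
    row("hemoglobin",         TRUE, FALSE, FALSE, 10.5, 1.8, "mean"),
    row("wbc_count",          TRUE, FALSE, FALSE,  12,    5, "mean"),
    row("platelets_count",    TRUE, FALSE, FALSE, 200,   80, "mean"),
    row("ptt",                TRUE, FALSE, FALSE,  35,   12, "mean"),
    row("pt",                 TRUE, FALSE, FALSE,  15,    4, "mean"),
    row("inr",                TRUE, FALSE, FALSE, 1.4,  0.4, "mean"),
    row("arterial_ph",        TRUE, FALSE, FALSE, 7.38, 0.06, "mean"),
    row("pao2",               TRUE, FALSE, FALSE, 120,   40, "mean"),
    row("paco2",              TRUE, FALSE, FALSE,  40,    8, "mean"),
    row("arterial_be",        TRUE, FALSE, FALSE,   0,    4, "mean"),
    row("bicarbonate",        TRUE, FALSE, FALSE,  23,    4, "mean"),
    row("lactate",            TRUE, FALSE, FALSE, 2.2,  1.5, "mean")
  )
}

#' Default names of the 48 modelled features
#' @return Character vector of length 48.
#' @export
default_feature_names <- function() feature_catalog()$name

#' Cardiorespiratory feature subset
#'
#' The six bedside-monitoring features continuously available in the ICU:
#' heart rate, systolic and diastolic blood pressure, shock index (heart rate
#' over systolic pressure), peripheral oxygen saturation, and mechanical
#' ventilation.
#' @return Character vector of length 6.
#' @export
cardio_features <- function() {
  c("heart_rate", "systolic_bp", "diastolic_bp", "shock_index", "spo2",
    "mech_vent")
}

#' Low-information reference feature subset
#'
#' Six features used as a comparison set of equal dimensionality to
#' [cardio_features()] but with low loading on the leading principal
#' component: gender, total fluid input, chloride, body temperature, weight
#' and readmission.
#' @return Character vector of length 6.
#' @export
baseline_features <- function() {
  c("gender", "total_fluid_input", "chloride", "body_temperature", "weight",
    "readmission")
}

#' Laboratory-derived features
#' @return Character vector (26 names).
#' @export
lab_features <- function() {
  cat <- feature_catalog()
  cat$name[cat$lab]
}

#' Features available without laboratory latency
#' @return Character vector (22 names).
#' @export
nolab_features <- function() {
  cat <- feature_catalog()
  cat$name[!cat$lab]
}

#' Default physiological capping bounds
#'
#' Plausible-value bounds per feature, in native units, used to clamp raw
#' measurements before state construction. Continuous features are bounded at
#' base value plus/minus five scale units; 0/1 features at `[0, 1]`; bounded
#' physiological quantities (SpO2, arterial pH, FiO2) at their physical
#' ranges.
#'
#' @return Named list mapping feature name to `c(low, high)`.
#' @export
default_cap_bounds <- function() {
  cat <- feature_catalog()
  b <- lapply(seq_len(nrow(cat)), function(i) {
    if (cat$binary[i]) return(c(0, 1))
    c(cat$base[i] - 5 * cat$scale[i], cat$base[i] + 5 * cat$scale[i])
  })
  names(b) <- cat$name
  b$spo2 <- c(0, 100)
  b$fio2 <- c(0.21, 1)
  b$arterial_ph <- c(6.8, 7.8)
  b$gcs <- c(3, 15)
  b
}

#' Default within-bin aggregation rules
#'
#' Flow-like variables (urine output, fluid input, fluid balance) are summed
#' within a 4-hour bin; level-like variables are averaged.
#'
#' @return Named character vector mapping feature name to `"mean"` or
#'   `"sum"`.
#' @export
default_aggregation <- function() {
  cat <- feature_catalog()
  stats::setNames(cat$agg, cat$name)
}
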