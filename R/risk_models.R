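# Per-condition annual incidence risk models.
#
# Five score families map an individual profile to an annual hazard:
#   cvd              - Globorisk-style laboratory score, averaging three
#                      country-specific 10-year risks (Jordan, Lebanon,
#                      Syria) in probability space, then converting to a
#                      constant annual hazard;
#   diabetes         - FINDRISC categorical points mapped to a 10-year risk;
#   asthma_copd      - multiplicative model: age-specific baseline hazard x
#                      prior-diagnosis RR x smoke-exposure RR;
#   breast_cancer    - Gail-style age-specific baseline x relative-risk
#                      multipliers (women only);
#   colorectal_cancer- CRC-PRO-style multiplicative model on age, sex,
#                      smoking and adiposity.
#
# Coefficient sets are replaceable fixtures (inst/extdata/
# risk_coefficients.json); downstream calibration rescales each hazard to
# external burden targets, so modest coefficient differences are absorbed.

CONDITIONS <- c("cvd", "diabetes", "asthma_copd", "breast_cancer",
                "colorectal_cancer")

#' The five modeled conditions
#' @return Character vector of condition codes.
#' @export
conditions <- function() CONDITIONS

#' Load the shipped risk-score coefficient fixture
#' @param path Path to a JSON coefficient registry (default: shipped file).
#' @return Named list of per-condition coefficient sets.
#' @export
risk_coefficients <- function(path = system.file("extdata",
                                                 "risk_coefficients.json",
                                                 package = "ncdsim")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Construct a condition model
#'
#' @param condition One of [conditions()].
#' @param score_family Score family identifier (informational).
#' @param coefficients Named coefficient list for the family.
#' @param calibration_scale Positive multiplicative hazard scale (default 1;
#'   set by [calibrate()]).
#' @param case_fatality Annual case-fatality probability among prevalent
#'   cases (before calibration).
#' @param cf_scale Positive multiplicative case-fatality scale (default 1).
#' @return An object of class `ncd_condition_model`.
#' @export
condition_model <- function(condition, score_family, coefficients,
                            calibration_scale = 1, case_fatality = 0.01,
                            cf_scale = 1) {
  condition <- match.arg(condition, CONDITIONS)
  if (!is.numeric(calibration_scale) || calibration_scale < 0)
    stop("calibration_scale must be >= 0", call. = FALSE)
  if (!is.numeric(cf_scale) || cf_scale < 0)
    stop("cf_scale must be >= 0", call. = FALSE)
  structure(list(condition = condition, score_family = score_family,
                 coefficients = coefficients,
                 calibration_scale = calibration_scale,
                 case_fatality = case_fatality, cf_scale = cf_scale),
            class = "ncd_condition_model")
}

#' Default condition-model registry
#'
#' Builds the five condition models from the shipped coefficient fixture,
#' with calibration scales of 1 (uncalibrated).
#'
#' @param coefficients Coefficient registry, see [risk_coefficients()].
#' @return Named list of `ncd_condition_model`s keyed by condition.
#' @export
default_condition_models <- function(coefficients = risk_coefficients()) {
  fams <- c(cvd = "globorisk_lab_mean3", diabetes = "findrisc",
            asthma_copd = "rr_multiplicative", breast_cancer = "gail_style",
            colorectal_cancer = "crcpro_style")
  out <- lapply(CONDITIONS, function(cn)
    condition_model(cn, fams[[cn]], coefficients[[cn]],
                    case_fatality = coefficients[[cn]]$case_fatality))
  names(out) <- CONDITIONS
  out
}

required_fields <- function(family) {
  switch(family,
         globorisk_lab_mean3 = c("age", "sex", "sbp", "total_chol", "smoker",
                                 "dx_diabetes"),
         findrisc = c("age", "bmi", "rx_hypertension"),
         rr_multiplicative = c("age", "smoker"),
         gail_style = c("age", "sex"),
         crcpro_style = c("age", "sex", "smoker", "bmi"),
         stop("unknown score family: ", family, call. = FALSE))
}

check_profile <- function(profile, family) {
  need <- required_fields(family)
  missing_col <- setdiff(need, names(profile))
  if (length(missing_col) > 0)
    stop(sprintf("profile lacks field(s) required by %s: %s",
                 family, paste(missing_col, collapse = ", ")), call. = FALSE)
  for (v in need) {
    if (anyNA(profile[[v]]))
      stop(sprintf("profile field '%s' required by %s contains missing values",
                   v, family), call. = FALSE)
  }
  invisible(TRUE)
}

# ---- family hazards (annual, uncalibrated) --------------------------------

hazard_globorisk <- function(profile, cf, age = profile$age) {
  lp <- cf$b_age * (age - 60) +
    cf$b_male * (profile$sex == "male") +
    cf$b_sbp * (profile$sbp - 120) / 10 +
    cf$b_tc * (profile$total_chol - 200) / 40 +
    cf$b_smoke * profile$smoker +
    cf$b_dm * profile$dx_diabetes
  p10 <- sapply(cf$country_h0, function(h0) 1 - exp(-h0 * exp(lp)))
  if (is.null(dim(p10))) p10 <- matrix(p10, nrow = 1)
  p10m <- rowMeans(p10)
  -log(1 - pmin(p10m, 0.999)) / 10
}

#' FINDRISC categorical points
#'
#' Integer diabetes-risk points from age band, BMI band (the BMI band also
#' carries the waist-circumference points, since waist is not surveyed) and
#' blood-pressure medication use. Unsurveyed items (physical activity, diet,
#' glucose history, family history) contribute population-average zero
#' points.
#'
#' @param profile Data frame of individual records (needs `age`, `bmi`,
#'   `rx_hypertension`).
#' @return Integer vector of points (>= 0).
#' @export
findrisc_points <- function(profile) {
  check_profile(profile, "findrisc")
  age_pts <- ifelse(profile$age < 45, 0L,
                    ifelse(profile$age <= 54, 2L,
                           ifelse(profile$age <= 64, 3L, 4L)))
  bmi_pts <- ifelse(profile$bmi < 25, 0L, ifelse(profile$bmi <= 30, 1L, 3L))
  waist_pts <- ifelse(profile$bmi < 25, 0L, ifelse(profile$bmi <= 30, 3L, 4L))
  bp_pts <- ifelse(profile$rx_hypertension, 2L, 0L)
  as.integer(age_pts + bmi_pts + waist_pts + bp_pts)
}

hazard_findrisc <- function(profile, cf, age = profile$age) {
  prof <- profile
  prof$age <- age
  pts <- findrisc_points(prof)
  cuts <- cf$points_cut    # upper bounds of point bands
  p10 <- cf$risk10         # 10-year risk per band
  band <- findInterval(pts, cuts) + 1L
  -log(1 - p10[band]) / 10
}

#' Smoke-exposure rate ratio
#'
#' Multiplicative rate ratio applied to cardiovascular and asthma/COPD
#' hazards: active smoking and second-hand exposure contribute independent
#' ratios whose product is applied; a person with neither exposure gets 1.
#'
#' @param profile Data frame with a `smoker` column.
#' @param context List with `secondhand_exposed` (logical, recycled).
#' @param rr_active,rr_secondhand Positive rate ratios.
#' @return Numeric vector of rate ratios (> 0).
#' @export
smoke_exposure_rr <- function(profile,
                              context = list(secondhand_exposed = FALSE),
                              rr_active = 1.5, rr_secondhand = 1.2) {
  if (rr_active <= 0 || rr_secondhand <= 0)
    stop("smoke-exposure rate ratios must be > 0", call. = FALSE)
  sh <- context$secondhand_exposed
  if (is.null(sh)) sh <- FALSE
  sh <- rep_len(as.logical(sh), nrow(profile))
  rr_active^profile$smoker * rr_secondhand^sh
}

hazard_asthma_copd <- function(profile, cf, age = profile$age) {
  rr_smoke <- smoke_exposure_rr(profile, rr_active = cf$rr_active_smoke,
                                rr_secondhand = cf$rr_secondhand)
  cf$h0 * exp(cf$b_age * (age - 60)) * rr_smoke
}

hazard_breast <- function(profile, cf, age = profile$age) {
  rr <- if (is.null(cf$rr_multiplier)) 1 else cf$rr_multiplier
  h <- cf$h0 * exp(cf$b_age * (age - 55)) * rr
  h * (profile$sex == "female")
}

hazard_crc <- function(profile, cf, age = profile$age) {
  cf$h0 * exp(cf$b_age * (age - 60)) *
    ifelse(profile$sex == "male", cf$rr_male, 1) *
    ifelse(profile$smoker, cf$rr_smoker, 1) *
    ifelse(profile$bmi > 30, cf$rr_obese, 1)
}

#' Uncalibrated annual hazard for a condition model
#'
#' @param model An `ncd_condition_model`.
#' @param profile Data frame of individual records.
#' @param age Optional age vector overriding `profile$age` (used to age the
#'   cohort during simulation).
#' @return Nonnegative annual hazard per record.
#' @export
base_hazard <- function(model, profile, age = profile$age) {
  check_profile(profile, model$score_family)
  h <- switch(model$score_family,
              globorisk_lab_mean3 = hazard_globorisk(profile,
                                                     model$coefficients, age),
              findrisc = hazard_findrisc(profile, model$coefficients, age),
              rr_multiplicative = hazard_asthma_copd(profile,
                                                     model$coefficients, age),
              gail_style = hazard_breast(profile, model$coefficients, age),
              crcpro_style = hazard_crc(profile, model$coefficients, age))
  pmax(h, 0)
}

#' Annual incidence probability for a condition model
#'
#' Converts the calibrated hazard to an annual probability,
#' `1 - exp(-calibration_scale * hazard)`, guaranteed in `[0, 1]` and
#' monotone nondecreasing in each adverse factor the score family uses.
#' Missing required fields raise an explicit error (no silent default).
#'
#' @inheritParams base_hazard
#' @return Annual probability per record.
#' @export
annual_risk <- function(model, profile, age = profile$age) {
  1 - exp(-model$calibration_scale * base_hazard(model, profile, age))
}
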