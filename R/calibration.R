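# Calibration of hazard scales to external burden targets.
#
# One multiplicative scale per condition is solved so the expected ten-year
# cumulative incidence per 10,000 matches its target; a second,
# case-fatality scale then matches the mortality target holding the
# incidence scale fixed. The default objective is a deterministic
# mean-field expectation (per-individual survival and condition-probability
# propagation through the same annual-cycle structure as the stochastic
# engine), which is smooth and exactly monotone in the scale, so bisection
# converges without a Monte-Carlo noise floor. A stochastic
# common-random-number objective is available for cross-checks.

#' Construct a calibration target
#'
#' @param condition One of [conditions()].
#' @param incidence Target cumulative incident cases per 10,000 over the
#'   horizon (>= 0).
#' @param mortality Target condition-attributed deaths per 10,000 over the
#'   horizon (>= 0; may exceed incidence because deaths can arise from
#'   prevalent disease, but not the population size).
#' @param tolerance Relative tolerance (default 2%).
#' @return An object of class `ncd_target`.
#' @export
calibration_target <- function(condition, incidence, mortality,
                               tolerance = 0.02) {
  condition <- match.arg(condition, CONDITIONS)
  stopifnot(incidence >= 0, mortality >= 0, mortality <= 10000)
  structure(list(condition = condition, incidence = incidence,
                 mortality = mortality, tolerance = tolerance),
            class = "ncd_target")
}

#' Default calibration targets from the shipped burden panel
#' @param panel Burden panel data frame, see [baseline_burden_panel()].
#' @return Named list of `ncd_target`s keyed by condition.
#' @export
default_calibration_targets <- function(panel = baseline_burden_panel()) {
  out <- lapply(seq_len(nrow(panel)), function(i)
    calibration_target(panel$condition[i], panel$incidence[i],
                       panel$mortality[i]))
  names(out) <- panel$condition
  out
}

#' Expected cumulative incidence and mortality per 10,000 (mean-field)
#'
#' Propagates, for each individual, the probability of being alive and the
#' marginal probability of carrying each condition through the annual
#' cycle (competing mortality first, then incidence among survivors),
#' without Monte-Carlo noise. Used as the calibration objective and as a
#' cross-check on the stochastic engine.
#'
#' @param pop Population data frame.
#' @param models Named list of `ncd_condition_model`s.
#' @param daly_params An `ncd_daly_params` (for other-cause mortality).
#' @param horizon Years.
#' @param hazards Optional precomputed list of per-condition hazard
#'   matrices (see the engine internals); recomputed when `NULL`.
#' @return List with numeric vectors `incidence` and `deaths` (per 10,000,
#'   named by condition) and `other_deaths`.
#' @export
expected_rates <- function(pop, models, daly_params = daly_parameters(),
                           horizon = 10L, hazards = NULL) {
  n <- nrow(pop)
  nc <- length(CONDITIONS)
  Hbase <- hazards %||% precompute_hazards(pop, models, horizon)
  scales <- vapply(models, `[[`, numeric(1), "calibration_scale")
  cf <- vapply(models, function(m) m$case_fatality * m$cf_scale, numeric(1))
  a <- rep(1, n)                         # P(alive at start of year)
  pi_c <- prevalent_matrix(pop) * 1.0    # P(condition | alive)
  inc <- stats::setNames(numeric(nc), CONDITIONS)
  dth <- stats::setNames(numeric(nc), CONDITIONS)
  other <- 0
  for (t in 0:(horizon - 1L)) {
    h_oc <- other_cause_hazard(daly_params, pop$age + t, pop$sex)
    hcf <- sweep(pi_c, 2, cf, `*`)       # expected cf hazard contribution
    S <- rowSums(hcf)
    # per-condition: a case faces h_oc + its own cf + the expected cf of the
    # other conditions; cause allocation follows the competing-hazard form
    for (j in seq_len(nc)) {
      H_with <- h_oc + (S - hcf[, j]) + cf[j]
      d_with <- 1 - exp(-H_with)
      dth[j] <- dth[j] + sum(a * pi_c[, j] * d_with * cf[j] / H_with)
    }
    Htot <- h_oc + S
    other <- other + sum(a * (1 - exp(-Htot)) * h_oc / Htot)
    # mean-field survival under within-individual independence of conditions,
    # with condition prevalence depleted among survivors (cases die faster)
    s_cond <- 1 - sweep(pi_c, 2, 1 - exp(-cf), `*`)  # 1-pi + pi*exp(-cf)
    s_i <- exp(-h_oc) * apply(s_cond, 1, prod)
    pi_next <- sweep(pi_c, 2, exp(-cf), `*`) / s_cond
    a_surv <- a * s_i
    for (j in seq_len(nc)) {
      p_inc <- 1 - exp(-scales[j] * Hbase[[j]][, t + 1L])
      new <- (1 - pi_next[, j]) * p_inc
      inc[j] <- inc[j] + sum(a_surv * new)
      pi_c[, j] <- pi_next[, j] + new
    }
    a <- a_surv
  }
  list(incidence = inc * 10000 / n, deaths = dth * 10000 / n,
       other_deaths = other * 10000 / n)
}

# generic monotone bisection with bracket expansion
bisect_scale <- function(f, target, tol, max_iter = 50L, lo = 1e-6,
                         hi = 16, what = "scale") {
  f_hi <- f(hi)
  expand <- 0L
  while (f_hi < target && expand < 12L) {
    hi <- hi * 4
    f_hi <- f(hi)
    expand <- expand + 1L
  }
  if (f_hi < target)
    stop(sprintf("calibration target unreachable (%s): max attainable %.1f < target %.1f",
                 what, f_hi, target), call. = FALSE)
  f_lo <- f(lo)
  if (f_lo > target) lo <- 0  # f(0) = 0 <= target always
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target) <= tol * max(target, 1e-12)) return(mid)
    if (fm < target) lo <- mid else hi <- mid
  }
  stop(sprintf("calibration did not converge after %d iterations (%s); last bracket [%.4g, %.4g]",
               max_iter, what, lo, hi), call. = FALSE)
}

#' Calibrate one condition model to its burden target
#'
#' Solves the multiplicative hazard scale so the expected cumulative
#' incidence per 10,000 over the horizon matches `target$incidence` within
#' `target$tolerance`, then solves the case-fatality scale for
#' `target$mortality` holding the incidence scale fixed. Aggregate targets
#' are matched with a single global scale; age/sex gradients are carried by
#' the risk scores themselves.
#'
#' @param pop Population data frame.
#' @param model The `ncd_condition_model` to calibrate.
#' @param target An `ncd_target` for the same condition.
#' @param daly_params An `ncd_daly_params`.
#' @param horizon Years.
#' @param models_context Other conditions' models (for the shared mortality
#'   field); defaults to uncalibrated copies.
#' @param objective `"expectation"` (deterministic mean-field, default) or
#'   `"simulation"` (stochastic engine under common random numbers).
#' @param config Simulation config used when `objective = "simulation"`.
#' @return The model with `calibration_scale` and `cf_scale` set; attribute
#'   `achieved` carries the attained incidence and mortality.
#' @export
calibrate <- function(pop, model, target, daly_params = daly_parameters(),
                      horizon = 10L, models_context = NULL,
                      objective = c("expectation", "simulation"),
                      config = sim_config(seed = 1L)) {
  objective <- match.arg(objective)
  stopifnot(model$condition == target$condition)
  if (is.null(models_context)) {
    models_context <- default_condition_models()
  }
  models_context[[model$condition]] <- model
  cn <- model$condition

  hz <- if (objective == "expectation")
    precompute_hazards(pop, models_context, horizon) else NULL
  measure <- function(models) {
    if (objective == "expectation") {
      expected_rates(pop, models, daly_params, horizon, hazards = hz)
    } else {
      res <- run_simulation_once(pop, models, daly_params,
                                 sim_config(horizon_years = horizon,
                                            discount_rate = config$discount_rate,
                                            seed = config$seed))
      list(incidence = stats::setNames(res$incidence[seq_along(CONDITIONS)],
                                       CONDITIONS),
           deaths = stats::setNames(res$mortality[seq_along(CONDITIONS)],
                                    CONDITIONS))
    }
  }

  if (target$incidence > 0) {
    f_inc <- function(s) {
      models_context[[cn]]$calibration_scale <- s
      measure(models_context)$incidence[[cn]]
    }
    model$calibration_scale <- bisect_scale(
      f_inc, target$incidence, target$tolerance,
      what = paste0(cn, " incidence"))
  } else {
    model$calibration_scale <- 0
  }
  models_context[[cn]] <- model

  if (target$mortality > 0) {
    f_mort <- function(s) {
      models_context[[cn]]$cf_scale <- s
      measure(models_context)$deaths[[cn]]
    }
    model$cf_scale <- bisect_scale(
      f_mort, target$mortality, target$tolerance,
      what = paste0(cn, " mortality"))
  } else {
    model$cf_scale <- 0
  }
  models_context[[cn]] <- model
  attr(model, "achieved") <- measure(models_context)
  model
}

#' Calibrate all condition models to a target set
#'
#' Calibrates each condition in turn (incidence scale, then case-fatality
#' scale) against the shared mortality field, with a second pass to absorb
#' the small cross-condition competing-risk interactions.
#'
#' @inheritParams calibrate
#' @param models Named list of `ncd_condition_model`s.
#' @param targets Named list of `ncd_target`s (default: shipped panel).
#' @param passes Number of sweeps over the conditions.
#' @return Named list of calibrated models.
#' @export
calibrate_models <- function(pop, models = default_condition_models(),
                             targets = default_calibration_targets(),
                             daly_params = daly_parameters(), horizon = 10L,
                             passes = 2L, ...) {
  for (p in seq_len(passes)) {
    for (cn in names(targets)) {
      models[[cn]] <- calibrate(pop, models[[cn]], targets[[cn]],
                                daly_params, horizon,
                                models_context = models, ...)
    }
  }
  models
}
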