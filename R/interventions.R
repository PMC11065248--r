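# The nine modeled WHO interventions: mechanism, eligibility, reach, costs.

#' Construct a reach curve
#'
#' Population reach of an intervention per simulation year. Three ramps are
#' supported:
#' * `"immediate"` — constant `reach` from year 0;
#' * `"linear_over_horizon"` — scale-up from zero to `reach`:
#'   `reach * (t+1) / horizon`;
#' * `"linear_from_start"` — start at the `reach` floor and scale linearly
#'   to full coverage: `min(1, reach + (1-reach) * (t+1) / horizon)`
#'   (the library default, reading "starting from a 64% reach rate with a
#'   linear implementation period" literally);
#' * `"custom"` — an explicit nondecreasing schedule in `[0,1]`.
#'
#' @param reach Headline reach fraction in `[0,1]` (default 0.64).
#' @param ramp One of the ramp types above.
#' @param schedule Numeric vector of per-year reach values for
#'   `ramp = "custom"`.
#' @return An object of class `ncd_reach`.
#' @export
reach_curve <- function(reach = 0.64,
                        ramp = c("linear_from_start", "immediate",
                                 "linear_over_horizon", "custom"),
                        schedule = NULL) {
  ramp <- match.arg(ramp)
  if (!is.numeric(reach) || reach < 0 || reach > 1)
    stop("reach must lie in [0, 1]", call. = FALSE)
  if (ramp == "custom") {
    if (is.null(schedule) || any(schedule < 0 | schedule > 1) ||
        is.unsorted(schedule))
      stop("custom schedule must be nondecreasing within [0, 1]",
           call. = FALSE)
  }
  structure(list(reach = reach, ramp = ramp, schedule = schedule),
            class = "ncd_reach")
}

#' Reach in a given simulation year
#'
#' @param curve An `ncd_reach`.
#' @param year 0-based year index (vectorized), within `0..horizon-1`.
#' @param horizon Policy horizon in years.
#' @return Reach fraction(s) in `[0,1]`, nondecreasing in `year`.
#' @export
reach <- function(curve, year, horizon = 10L) {
  if (any(year < 0 | year > horizon - 1L))
    stop("year out of range 0..horizon-1", call. = FALSE)
  switch(curve$ramp,
         immediate = rep_len(curve$reach, length(year)),
         linear_over_horizon = curve$reach * (year + 1) / horizon,
         linear_from_start = pmin(1, curve$reach +
                                    (1 - curve$reach) * (year + 1) / horizon),
         custom = curve$schedule[year + 1L])
}

#' Construct an intervention specification
#'
#' @param who_id WHO intervention list label (e.g. `"1.4"`).
#' @param label Human-readable description.
#' @param mechanism List of effects, each a list with `target` (condition),
#'   `channel` (`"incidence_rr"`, `"mortality_rr"` or `"factor_shift"`) and
#'   `rr` (positive rate ratio) or `field`/`magnitude` for factor shifts.
#' @param eligibility List with `type` in `"all"`, `"female_age_band"`
#'   (fields `age_lo`, `age_hi`), `"dx_flag"` (field `field`) or
#'   `"incident_case"` (field `target`); total over all records.
#' @param cost_model List with `basis` (`"per_person_year"`,
#'   `"per_eligible_person_year"` or `"per_incident_case"`), `unit_cost`
#'   (2023 international dollars, >= 0), optional `program_fixed` ($/year)
#'   and `eligible_fraction`.
#' @param reach An `ncd_reach` curve.
#' @return An object of class `ncd_intervention`.
#' @export
intervention_spec <- function(who_id, label = who_id, mechanism,
                              eligibility = list(type = "all"),
                              cost_model, reach = reach_curve()) {
  for (m in mechanism) {
    if (m$channel %in% c("incidence_rr", "mortality_rr") && m$rr <= 0)
      stop("rate ratios must be > 0 (", who_id, ", ", m$target, ")",
           call. = FALSE)
    if (!m$target %in% CONDITIONS)
      stop("unknown mechanism target: ", m$target, call. = FALSE)
  }
  if (cost_model$unit_cost < 0 ||
      (!is.null(cost_model$program_fixed) && cost_model$program_fixed < 0))
    stop("costs must be >= 0", call. = FALSE)
  structure(list(who_id = who_id, label = label, mechanism = mechanism,
                 eligibility = eligibility, cost_model = cost_model,
                 reach = reach),
            class = "ncd_intervention")
}

eligibility_mask <- function(elig, pop, age_t = pop$age) {
  switch(elig$type,
         all = rep(TRUE, nrow(pop)),
         female_age_band = pop$sex == "female" &
           age_t >= elig$age_lo & age_t <= elig$age_hi,
         dx_flag = as.logical(pop[[elig$field]]),
         incident_case = rep(TRUE, nrow(pop)),
         stop("unknown eligibility type: ", elig$type, call. = FALSE))
}

#' The nine-intervention library
#'
#' Loads the default specifications of the nine WHO interventions judged
#' feasible for modeling in Gaza, with the published unit costs and
#' replaceable literature-style effect defaults.
#'
#' @param path JSON fixture path (default: shipped file).
#' @param reach Default reach curve applied to every intervention.
#' @return Named list of nine `ncd_intervention`s keyed by `who_id`.
#' @export
intervention_library <- function(path = system.file("extdata",
                                                    "interventions.json",
                                                    package = "ncdsim"),
                                 reach = reach_curve()) {
  raw <- jsonlite::read_json(path)$interventions
  out <- lapply(raw, function(x)
    intervention_spec(x$who_id, x$label,
                      mechanism = x$mechanism,
                      eligibility = x$eligibility,
                      cost_model = x$cost_model,
                      reach = reach))
  names(out) <- vapply(out, `[[`, "", "who_id")
  out
}

#' Adjust annual probabilities for an intervention
#'
#' Applies an intervention's rate ratios to one year's per-condition annual
#' probabilities on the hazard scale and returns the accrued per-person
#' cost. In `"expectation"` mode the hazard multiplier is the reach mixture
#' `1 - reach(t) * (1 - rr)` for an eligible individual; in `"rng"` mode a
#' reach draw decides whether the full rate ratio applies.
#'
#' @param annual_probs Named numeric vector of annual probabilities, named
#'   by condition, each in `[0,1]`. Names `inc_<condition>` /
#'   `mort_<condition>` select the channel; bare condition names are
#'   treated as incidence.
#' @param spec An `ncd_intervention`.
#' @param year 0-based year index.
#' @param eligible Logical: does the individual satisfy the eligibility
#'   predicate this year?
#' @param mode `"expectation"` (default) or `"rng"`.
#' @param horizon Policy horizon.
#' @param u Uniform deviate for `"rng"` mode.
#' @return List with `probs` (adjusted vector) and `cost` (dollars accrued
#'   this year for this individual, undiscounted).
#' @export
apply_intervention <- function(annual_probs, spec, year, eligible = TRUE,
                               mode = c("expectation", "rng"),
                               horizon = 10L, u = NULL) {
  mode <- match.arg(mode)
  if (any(annual_probs < 0 | annual_probs > 1))
    stop("annual probabilities must lie in [0, 1]", call. = FALSE)
  r_t <- reach(spec$reach, year, horizon)
  reached <- if (mode == "rng") {
    if (is.null(u)) u <- stats::runif(1)
    u < r_t
  } else TRUE
  probs <- annual_probs
  for (m in spec$mechanism) {
    if (!m$channel %in% c("incidence_rr", "mortality_rr"))
      stop("unknown channel: ", m$channel, call. = FALSE)
    keys <- c(m$target,
              paste0(if (m$channel == "incidence_rr") "inc_" else "mort_",
                     m$target))
    key <- intersect(keys, names(probs))
    if (length(key) == 0) next
    mult <- if (!eligible || !reached) 1
    else if (mode == "rng") m$rr
    else 1 - r_t * (1 - m$rr)
    if (mult != 1)
      probs[key] <- 1 - exp(-(-log(1 - probs[key])) * mult)
  }
  cm <- spec$cost_model
  indiv_cost <- switch(cm$basis,
                       per_person_year = cm$unit_cost,
                       per_eligible_person_year =
                         if (eligible) cm$unit_cost else 0,
                       per_incident_case = 0)
  cost <- if (mode == "rng") (if (reached && eligible) indiv_cost else 0)
  else r_t * (if (eligible) indiv_cost else 0)
  list(probs = probs, cost = cost)
}
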