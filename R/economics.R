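# Discounted costs, ICERs, threshold classification, CE-plane export.
# All monetary quantities are 2023 international dollars.

#' Willingness-to-pay constants
#'
#' GDP per capita used for cost-effectiveness banding; the conventional
#' threshold is three times GDP per capita per DALY averted ($10,992 here).
#' @export
GDP_PER_CAPITA <- 3664

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental discounted cost ($).
#' @param delta_dalys_averted Incremental discounted DALYs averted.
#' @return The ratio ($ per DALY averted) when both are positive;
#'   `"dominant"` when cost <= 0 with DALYs averted > 0; `"dominated"` when
#'   DALYs averted <= 0 with cost > 0; `"undefined"` for 0/0.
#' @export
icer <- function(delta_cost, delta_dalys_averted) {
  if (!is.finite(delta_cost) || !is.finite(delta_dalys_averted))
    stop("icer() requires finite inputs", call. = FALSE)
  if (delta_dalys_averted > 0 && delta_cost > 0)
    return(delta_cost / delta_dalys_averted)
  if (delta_dalys_averted > 0) return("dominant")
  if (delta_cost > 0) return("dominated")
  if (delta_cost <= 0 && delta_dalys_averted < 0) return("dominated")
  "undefined"
}

#' Classify an ICER against GDP-based thresholds
#'
#' Exclusive ordered bands; a boundary value falls in the lower band
#' (`<=` is "below"). Dominant interventions classify in the lowest band,
#' dominated in the highest.
#'
#' @param icer_value Numeric ICER or a dominance label from [icer()].
#' @param gdp_per_capita GDP per capita (default such that three times
#'   equals $10,992).
#' @return One of `"below_1xGDP"`, `"below_3xGDP"`, `"above_3xGDP"`.
#' @export
classify_icer <- function(icer_value, gdp_per_capita = GDP_PER_CAPITA) {
  stopifnot(gdp_per_capita > 0)
  if (is.character(icer_value)) {
    return(switch(icer_value, dominant = "below_1xGDP",
                  dominated = "above_3xGDP", "above_3xGDP"))
  }
  if (icer_value <= gdp_per_capita) "below_1xGDP"
  else if (icer_value <= 3 * gdp_per_capita) "below_3xGDP"
  else "above_3xGDP"
}

#' Purchasing-power-parity cost adjustment
#'
#' Converts a cost quoted in another economy into local international
#' dollars by the GDP-PPP-per-capita ratio.
#'
#' @param cost_foreign Cost in the source economy.
#' @param ppp_ratio Positive ratio (local / source).
#' @return Adjusted cost.
#' @export
ppp_adjust <- function(cost_foreign, ppp_ratio) {
  if (any(ppp_ratio <= 0)) stop("ppp_ratio must be > 0", call. = FALSE)
  cost_foreign * ppp_ratio
}

#' Discounted intervention cost over the horizon
#'
#' Accrues the intervention's unit cost per its cost basis across the
#' reach-weighted population and discounts annually:
#' * `per_person_year`: unit cost x population x reach(t), each year;
#' * `per_eligible_person_year`: as above over the eligible fraction;
#' * `per_incident_case`: unit cost x reached incident cases of the target
#'   condition, with baseline incidence spread uniformly over the horizon;
#' plus any fixed program cost per year.
#'
#' @param spec An `ncd_intervention`.
#' @param population Adults simulated (default 10,000).
#' @param horizon Years.
#' @param discount_rate Annual discount rate.
#' @param baseline_incidence Ten-year incident cases per 10,000 of the
#'   cost-relevant condition (needed for `per_incident_case`; defaults to
#'   the shipped burden panel).
#' @param eligible_fraction Population fraction eligible (defaults to the
#'   spec's `cost_model$eligible_fraction`).
#' @return Discounted cost in dollars for the stated population.
#' @export
discounted_intervention_cost <- function(spec, population = 10000,
                                         horizon = 10L, discount_rate = 0.03,
                                         baseline_incidence = NULL,
                                         eligible_fraction = NULL) {
  cm <- spec$cost_model
  t <- 0:(horizon - 1L)
  disc <- (1 + discount_rate)^(-t)
  r_t <- reach(spec$reach, t, horizon)
  per_year <- switch(
    cm$basis,
    per_person_year = cm$unit_cost * population * r_t,
    per_eligible_person_year = {
      ef <- eligible_fraction %||% cm$eligible_fraction
      if (is.null(ef)) stop("eligible_fraction required for basis ",
                            cm$basis, call. = FALSE)
      cm$unit_cost * population * ef * r_t
    },
    per_incident_case = {
      if (is.null(baseline_incidence)) {
        panel <- baseline_burden_panel()
        baseline_incidence <-
          panel$incidence[panel$condition == spec$eligibility$target]
      }
      cases_per_year <- baseline_incidence / horizon * population / 10000
      cm$unit_cost * cases_per_year * r_t
    },
    stop("unknown cost basis: ", cm$basis, call. = FALSE))
  fixed <- cm$program_fixed %||% 0
  sum((per_year + fixed) * disc)
}

#' ICER for one intervention from panel-configured deltas
#'
#' Configures the scenario's DALYs averted from the effect panel (treated
#' as discounted), accrues the published unit cost over the reach-weighted
#' population with discounting, and computes the ICER and its threshold
#' classification.
#'
#' @param who_id Intervention id.
#' @param library Intervention library (see [intervention_library()]).
#' @param population,horizon,discount_rate Accrual settings.
#' @return One-row data frame: `who_id`, `dalys_averted`, `delta_cost`,
#'   `icer`, `classification`, `ci_low`, `ci_high` (DALY interval from the
#'   effect panel).
#' @export
panel_icer <- function(who_id, library = intervention_library(),
                       population = 10000, horizon = 10L,
                       discount_rate = 0.03) {
  spec <- library[[who_id]]
  if (is.null(spec)) stop("unknown intervention id: ", who_id, call. = FALSE)
  d <- panel_deltas(who_id)
  tot <- result_totals(d)
  cost <- discounted_intervention_cost(spec, population, horizon,
                                       discount_rate)
  ic <- icer(cost, tot$dalys_averted)
  data.frame(who_id = who_id,
             dalys_averted = tot$dalys_averted,
             delta_cost = cost,
             icer = if (is.character(ic)) NA_real_ else ic,
             dominance = if (is.character(ic)) ic else "ratio",
             classification = classify_icer(ic),
             ci_low = -tot$d_dalys_hi,
             ci_high = -tot$d_dalys_lo,
             stringsAsFactors = FALSE)
}

#' Cost-effectiveness league table / CE-plane export
#'
#' One row per intervention with discounted DALYs averted and incremental
#' cost, sorted by ICER ascending (dominant interventions first), ready for
#' plotting on the cost-effectiveness plane.
#'
#' @param who_ids Intervention ids (default: the full nine-intervention
#'   library).
#' @inheritParams panel_icer
#' @return Data frame of class `ncd_ce_plane`.
#' @export
cost_effectiveness_table <- function(who_ids = names(intervention_library()),
                                     library = intervention_library(),
                                     population = 10000, horizon = 10L,
                                     discount_rate = 0.03) {
  stopifnot(length(who_ids) > 0)
  rows <- lapply(who_ids, panel_icer, library = library,
                 population = population, horizon = horizon,
                 discount_rate = discount_rate)
  out <- do.call(rbind, rows)
  key <- ifelse(out$dominance == "dominant", -Inf,
                ifelse(out$dominance == "dominated", Inf, out$icer))
  out <- out[order(key), ]
  rownames(out) <- NULL
  class(out) <- c("ncd_ce_plane", "data.frame")
  out
}

#' Write the CE-plane table as CSV
#' @param x A `ncd_ce_plane` table.
#' @param path Output path.
#' @export
ce_plane_export <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
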