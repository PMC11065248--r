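# Probabilistic sensitivity analysis and reach sweeps.
#
# Parametric uncertainty propagation: input parameters are redrawn from
# truncated normal distributions (rate ratios on the log scale so draws
# stay positive) and the cost-effectiveness computation is re-run per
# draw. The desk-scale default re-runs the panel-configured economics
# (DALY deltas and unit costs resampled); an engine mode re-runs the
# stochastic scenario simulation per draw under common random numbers.

# truncated-normal sampler by rejection
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
    guard <- guard + 1L
  }
  if (length(bad) > 0) out[bad] <- pmin(pmax(out[bad], lo), hi)
  out
}

#' Default PSA distribution specification for one intervention
#'
#' DALYs averted: normal around the effect-panel total with SD from the
#' panel's 95% interval width. Unit cost: normal around the published unit
#' cost with a 25% coefficient of variation (a standard costing-uncertainty
#' assumption), truncated at zero.
#'
#' @param who_id Intervention id.
#' @param library Intervention library.
#' @param cost_cv Coefficient of variation on the unit cost.
#' @return List with `dalys` and `cost` entries (`mean`, `sd`, `lo`, `hi`).
#' @export
psa_defaults <- function(who_id, library = intervention_library(),
                         cost_cv = 0.25) {
  d <- result_totals(panel_deltas(who_id))
  unit <- library[[who_id]]$cost_model$unit_cost
  list(
    dalys = list(mean = d$dalys_averted,
                 sd = (d$dalys_averted > 0) *
                   abs(-d$d_dalys_lo - (-d$d_dalys_hi)) / (2 * 1.96),
                 lo = 0, hi = Inf),
    cost = list(mean = unit, sd = cost_cv * unit, lo = 0, hi = Inf)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Re-runs the cost-effectiveness computation `n_draws` times with
#' parameters resampled from `dist`, returning the mean and 2.5/97.5
#' percentiles of DALYs averted, incremental cost and the ICER.
#' Deterministic for fixed seed.
#'
#' @param who_id Intervention id.
#' @param n_draws Number of parameter draws (>= 1); the desk-scale default
#'   is 1,000.
#' @param seed Integer seed.
#' @param dist Distribution specification, see [psa_defaults()].
#' @param library Intervention library.
#' @param population,horizon,discount_rate Cost-accrual settings.
#' @param mode `"panel"` (resample DALY deltas and unit costs; default) or
#'   `"engine"` (resample mechanism rate ratios and unit costs and re-run
#'   the scenario simulation per draw under common random numbers; requires
#'   `pop`, `models`, `daly_params`, `config`).
#' @param rr_log_sd Log-scale SD for rate-ratio draws in engine mode.
#' @param pop,models,daly_params,config Engine-mode inputs.
#' @return An object of class `ncd_psa`: data frame with one row per
#'   quantity (`dalys_averted`, `delta_cost`, `icer`) and columns `mean`,
#'   `lo`, `hi`; attributes `n_draws`, `seed`, `draws`.
#' @export
run_psa <- function(who_id = "1.4", n_draws = 1000L, seed = 1L,
                    dist = psa_defaults(who_id, library),
                    library = intervention_library(),
                    population = 10000, horizon = 10L, discount_rate = 0.03,
                    mode = c("panel", "engine"), rr_log_sd = 0.1,
                    pop = NULL, models = NULL, daly_params = NULL,
                    config = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_draws >= 1)
  if (any(vapply(dist, function(d) d$sd < 0, logical(1))))
    stop("PSA distribution SDs must be >= 0", call. = FALSE)
  spec <- library[[who_id]]
  set.seed(seed)

  if (mode == "panel") {
    dalys <- rtruncnorm(n_draws, dist$dalys$mean, dist$dalys$sd,
                        dist$dalys$lo, dist$dalys$hi)
    units <- rtruncnorm(n_draws, dist$cost$mean, dist$cost$sd,
                        dist$cost$lo, dist$cost$hi)
    base_cost <- discounted_intervention_cost(spec, population, horizon,
                                              discount_rate)
    costs <- base_cost * units / spec$cost_model$unit_cost
  } else {
    stopifnot(!is.null(pop), !is.null(models), !is.null(config))
    if (is.null(daly_params)) daly_params <- daly_parameters()
    rrs <- vapply(spec$mechanism, `[[`, numeric(1), "rr")
    log_draws <- matrix(stats::rnorm(n_draws * length(rrs), log(rrs),
                                     rr_log_sd),
                        n_draws, byrow = TRUE)
    units <- rtruncnorm(n_draws, dist$cost$mean, dist$cost$sd,
                        dist$cost$lo, dist$cost$hi)
    baseline <- run_simulation(pop, models, daly_params, config, NULL)
    dalys <- numeric(n_draws)
    costs <- numeric(n_draws)
    for (i in seq_len(n_draws)) {
      sp <- spec
      for (k in seq_along(sp$mechanism))
        sp$mechanism[[k]]$rr <- min(exp(log_draws[i, k]), 1)
      sp$cost_model$unit_cost <- units[i]
      scen <- run_simulation(pop, models, daly_params, config, sp)
      d <- result_delta(scen, baseline)
      dalys[i] <- result_totals(d)$dalys_averted
      costs[i] <- attr(scen, "cost")
    }
  }

  icers <- ifelse(dalys > 0, costs / dalys, NA_real_)
  summ <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), stats::quantile(x, c(0.025, 0.975), names = FALSE))
  }
  out <- as.data.frame(rbind(dalys_averted = summ(dalys),
                             delta_cost = summ(costs),
                             icer = summ(icers)))
  names(out) <- c("mean", "lo", "hi")
  out <- cbind(quantity = rownames(out), out)
  rownames(out) <- NULL
  structure(out, class = c("ncd_psa", "data.frame"),
            who_id = who_id, n_draws = as.integer(n_draws), seed = seed,
            draws = data.frame(dalys_averted = dalys, delta_cost = costs,
                               icer = icers))
}

#' Reach sensitivity sweep
#'
#' Re-runs the scenario comparison at each reach value (same seed, common
#' random numbers) and reports DALYs averted, discounted cost and the
#' ICER. With purely per-person variable costs, DALYs and costs scale
#' linearly in reach and the ICER is invariant.
#'
#' @param reach_values Reach fractions in `[0,1]`.
#' @param spec An `ncd_intervention`.
#' @param pop,models,daly_params,config Engine inputs.
#' @param ramp Ramp type applied at every reach value.
#' @return Data frame with one row per reach value.
#' @export
reach_sweep <- function(reach_values, spec, pop, models,
                        daly_params = daly_parameters(),
                        config = sim_config(),
                        ramp = "linear_over_horizon") {
  if (any(reach_values < 0 | reach_values > 1))
    stop("reach values must lie in [0, 1]", call. = FALSE)
  base <- run_simulation(pop, models, daly_params, config, NULL)
  rows <- lapply(reach_values, function(rv) {
    sp <- spec
    sp$reach <- reach_curve(rv, ramp)
    scen <- run_simulation(pop, models, daly_params, config, sp)
    d <- result_totals(result_delta(scen, base))
    cost <- attr(scen, "cost")
    data.frame(reach = rv, dalys_averted = d$dalys_averted, cost = cost,
               icer = ifelse(d$dalys_averted > 0, cost / d$dalys_averted,
                             NA_real_))
  })
  do.call(rbind, rows)
}
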