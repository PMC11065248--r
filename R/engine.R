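# Individual-level annual-cycle microsimulation with competing risks.
#
# Within each simulated year: (1) mortality is resolved first by drawing a
# cause-specific exponential event time for every contending cause
# (condition case fatality among prevalent cases, plus other-cause
# mortality), so death probability is 1 - exp(-sum of hazards) and cause
# allocation follows h_i / sum(h) exactly; (2) incidence is drawn among
# survivors, per condition not yet active; (3) disability and life-year
# losses are accrued with discrete annual discounting (full weight in the
# onset year, half weight in the year of death).
#
# All uniforms are pre-drawn in a fixed order from the run seed, giving
# common random numbers across baseline and scenario runs: a null
# intervention reproduces the baseline bit-exactly.

#' Simulation configuration
#'
#' @param horizon_years Policy horizon in annual cycles (default 10).
#' @param population_size Reporting denominator basis; results are always
#'   normalised per 10,000 regardless of the simulated cohort size.
#' @param discount_rate Annual discount rate applied to both dollars and
#'   DALYs (default 3%).
#' @param seed Integer seed for the run.
#' @param replicates Number of replicate seeds; if > 1, results carry
#'   Monte-Carlo interval columns (2.5/97.5 percentiles over replicates).
#' @return An object of class `ncd_sim_config`.
#' @export
sim_config <- function(horizon_years = 10L, population_size = 10000L,
                       discount_rate = 0.03, seed = 1L, replicates = 1L) {
  stopifnot(horizon_years >= 1, discount_rate >= 0, population_size >= 1,
            replicates >= 1)
  structure(list(horizon_years = as.integer(horizon_years),
                 population_size = as.integer(population_size),
                 discount_rate = discount_rate, seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "ncd_sim_config")
}

#' Discounted annuity factor
#'
#' Present value of one unit per year over `years` years starting now:
#' `sum_(t=0..years-1) (1+rate)^(-t)`. Fractional years contribute their
#' fraction of the next (discounted) year.
#'
#' @param years Nonnegative duration (may be fractional); vectorized.
#' @param rate Nonnegative annual discount rate.
#' @return Annuity factor(s).
#' @export
discounted_annuity <- function(years, rate) {
  stopifnot(all(years >= 0), rate >= 0)
  full <- floor(years)
  frac <- years - full
  v <- 1 / (1 + rate)
  whole <- ifelse(rate == 0, full, (1 - v^full) / (1 - v))
  whole + frac * v^full
}

#' DALY parameters: disability weights, life table, background mortality
#'
#' Loads the per-condition disability weights and the abridged reference
#' life table (a synthetic GBD-style table shipped with the package,
#' replaceable), fits a Gompertz schedule `a * exp(b * age)` to the life
#' table death rates for use as other-cause mortality, and builds
#' sex-specific remaining-life-expectancy interpolators for years of life
#' lost.
#'
#' @param disability_weights Named numeric vector in `[0,1]` per condition,
#'   or `NULL` to read the shipped fixture.
#' @param life_table_path Path to a CSV with columns
#'   `age, mx_male, mx_female, ex_male, ex_female`.
#' @return An object of class `ncd_daly_params`.
#' @export
daly_parameters <- function(disability_weights = NULL,
                            life_table_path = system.file(
                              "extdata", "life_table_synthetic.csv",
                              package = "ncdsim")) {
  if (is.null(disability_weights)) {
    dwf <- utils::read.csv(system.file("extdata", "disability_weights.csv",
                                       package = "ncdsim"))
    disability_weights <- stats::setNames(dwf$disability_weight,
                                          dwf$condition)
  }
  if (any(disability_weights < 0 | disability_weights > 1))
    stop("disability weights must lie in [0, 1]", call. = FALSE)
  lt <- utils::read.csv(life_table_path)
  gfit <- function(mx) {
    fit <- stats::lm(log(mx) ~ age, data = data.frame(age = lt$age, mx = mx))
    c(a = exp(unname(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
  }
  structure(list(
    disability_weights = disability_weights,
    life_table = lt,
    gompertz = list(male = gfit(lt$mx_male), female = gfit(lt$mx_female)),
    le_male = stats::approxfun(lt$age, lt$ex_male, rule = 2),
    le_female = stats::approxfun(lt$age, lt$ex_female, rule = 2)
  ), class = "ncd_daly_params")
}

other_cause_hazard <- function(params, age, sex) {
  gm <- params$gompertz$male
  gf <- params$gompertz$female
  ifelse(sex == "female", gf[["a"]] * exp(gf[["b"]] * age),
         gm[["a"]] * exp(gm[["b"]] * age))
}

remaining_le <- function(params, age, sex) {
  ifelse(sex == "female", params$le_female(age), params$le_male(age))
}

# prevalent-at-baseline conditions carried by the survey diagnosis flags
prevalent_matrix <- function(pop) {
  cbind(cvd = rep(FALSE, nrow(pop)),
        diabetes = pop$dx_diabetes,
        asthma_copd = pop$dx_asthma_copd,
        breast_cancer = rep(FALSE, nrow(pop)),
        colorectal_cancer = rep(FALSE, nrow(pop)))
}

# n x horizon uncalibrated hazard matrix per condition, ageing the cohort
precompute_hazards <- function(pop, models, horizon) {
  lapply(models, function(m) {
    H <- vapply(seq_len(horizon) - 1L,
                function(t) base_hazard(m, pop, age = pop$age + t),
                numeric(nrow(pop)))
    matrix(H, nrow = nrow(pop))
  })
}

#' Compute discounted DALYs from simulation tallies
#'
#' `DALY = YLD + YLL`: years lived with each condition weighted by its
#' disability weight and discounted at `discount_rate` (onset year at full
#' weight, death year at half weight), plus discounted remaining life
#' expectancy at death for condition-attributed deaths.
#'
#' @param tallies Data frame with one row per (person, condition) episode:
#'   columns `condition`, `onset_year` (0-based), `death_year` (`NA` if
#'   alive at horizon end), `died_of_condition` (logical), `age_at_death`,
#'   `sex`, and attribute `horizon`.
#' @param daly_params An `ncd_daly_params`.
#' @param discount_rate Annual discount rate.
#' @return Data frame with `condition`, `yld`, `yll`, `dalys` (absolute
#'   person-years, not yet normalised per 10,000).
#' @export
compute_dalys <- function(tallies, daly_params, discount_rate = 0.03) {
  horizon <- attr(tallies, "horizon")
  if (is.null(horizon)) horizon <- 10L
  out <- data.frame(condition = CONDITIONS, yld = 0, yll = 0, dalys = 0)
  if (nrow(tallies) == 0) return(out)
  if (any(tallies$onset_year < 0, na.rm = TRUE) ||
      any(tallies$death_year < 0, na.rm = TRUE))
    stop("negative years in tallies", call. = FALSE)
  disc <- (1 + discount_rate)^(-(0:(horizon - 1L)))
  cumdisc <- cumsum(disc)
  span <- function(a, b) {  # sum of disc over years a..b (0-based)
    cumdisc[b + 1L] - c(0, cumdisc)[a + 1L]
  }
  died <- !is.na(tallies$death_year)
  last <- ifelse(died, tallies$death_year, horizon - 1L)
  yrs <- span(tallies$onset_year, last) -
    ifelse(died, 0.5 * disc[tallies$death_year + 1L], 0)
  dw <- daly_params$disability_weights[tallies$condition]
  yld_i <- dw * yrs
  yll_i <- rep(0, nrow(tallies))
  cd <- which(tallies$died_of_condition)
  if (length(cd) > 0) {
    le <- remaining_le(daly_params, tallies$age_at_death[cd],
                       tallies$sex[cd])
    yll_i[cd] <- discounted_annuity(le, discount_rate) *
      disc[tallies$death_year[cd] + 1L]
  }
  agg <- function(x) {
    s <- tapply(x, factor(tallies$condition, levels = CONDITIONS), sum)
    ifelse(is.na(s), 0, s)
  }
  out$yld <- as.numeric(agg(yld_i))
  out$yll <- as.numeric(agg(yll_i))
  out$dalys <- out$yld + out$yll
  out
}

# effective hazard multipliers for an intervention in year t (expectation
# mode): 1 - reach(t) * eligible * (1 - rr), per channel and condition
intervention_multipliers <- function(spec, pop, age_t, r_t) {
  n <- nrow(pop)
  inc <- matrix(1, n, length(CONDITIONS), dimnames = list(NULL, CONDITIONS))
  mort <- matrix(1, n, length(CONDITIONS), dimnames = list(NULL, CONDITIONS))
  if (is.null(spec)) return(list(inc = inc, mort = mort))
  elig <- eligibility_mask(spec$eligibility, pop, age_t)
  for (m in spec$mechanism) {
    mult <- 1 - r_t * elig * (1 - m$rr)
    if (m$channel == "incidence_rr") {
      inc[, m$target] <- inc[, m$target] * mult
    } else if (m$channel == "mortality_rr") {
      mort[, m$target] <- mort[, m$target] * mult
    } else if (m$channel != "factor_shift") {
      stop("unknown mechanism channel: ", m$channel, call. = FALSE)
    }
  }
  list(inc = inc, mort = mort, eligible = elig)
}

run_simulation_once <- function(pop, models, daly_params, config,
                                scenario = NULL, seed = config$seed) {
  n <- nrow(pop)
  stopifnot(n >= 1)
  H <- config$horizon_years
  r <- config$discount_rate
  nc <- length(CONDITIONS)
  if (!is.null(scenario)) {
    bad <- setdiff(vapply(scenario$mechanism, `[[`, "", "target"), CONDITIONS)
    if (length(bad) > 0)
      stop("scenario targets unknown condition(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  set.seed(seed)
  U_death <- array(stats::runif(n * H * (nc + 1L)), c(n, H, nc + 1L))
  U_inc <- array(stats::runif(n * H * nc), c(n, H, nc))

  Hbase <- precompute_hazards(pop, models, H)
  # factor_shift channels: blend hazards of a counterfactually shifted cohort
  Hshift <- NULL
  shift_targets <- character(0)
  if (!is.null(scenario)) {
    shifts <- Filter(function(m) m$channel == "factor_shift",
                     scenario$mechanism)
    if (length(shifts) > 0) {
      pop2 <- pop
      for (m in shifts) pop2[[m$field]] <- pop2[[m$field]] + m$magnitude
      shift_targets <- unique(vapply(shifts, `[[`, "", "target"))
      Hshift <- precompute_hazards(pop2, models, H)
    }
  }

  scales <- vapply(models, `[[`, numeric(1), "calibration_scale")
  cf <- vapply(models, function(m) m$case_fatality * m$cf_scale, numeric(1))

  active <- prevalent_matrix(pop)
  prevalent <- active
  onset <- matrix(NA_integer_, n, nc, dimnames = list(NULL, CONDITIONS))
  onset[prevalent] <- 0L
  alive <- rep(TRUE, n)
  death_year <- rep(NA_integer_, n)
  death_cause <- rep(NA_integer_, n)  # 1..nc conditions, nc+1 other
  disc <- (1 + r)^(-(0:(H - 1L)))
  cost <- 0

  for (t in 0:(H - 1L)) {
    age_t <- pop$age + t
    r_t <- if (is.null(scenario)) 0 else reach(scenario$reach, t, H)
    mults <- intervention_multipliers(scenario, pop, age_t, r_t)
    idx <- which(alive)
    if (length(idx) > 0) {
      # (1) competing mortality: cause-specific exponential event times
      haz <- matrix(0, length(idx), nc + 1L)
      for (j in seq_len(nc)) {
        haz[, j] <- ifelse(active[idx, j], cf[j] * mults$mort[idx, j], 0)
      }
      haz[, nc + 1L] <- other_cause_hazard(daly_params, age_t[idx],
                                           pop$sex[idx])
      if (any(haz < 0)) stop("negative mortality hazard", call. = FALSE)
      Uk <- matrix(U_death[idx, t + 1L, ], nrow = length(idx))
      Tk <- -log(Uk) / haz
      Tk[haz == 0] <- Inf
      tmin <- do.call(pmin, as.data.frame(Tk))
      dies <- tmin <= 1
      if (any(dies)) {
        kmin <- max.col(-Tk[dies, , drop = FALSE], ties.method = "first")
        who <- idx[dies]
        alive[who] <- FALSE
        death_year[who] <- t
        death_cause[who] <- kmin
      }
      # (2) incidence among survivors
      surv <- idx[!dies]
      if (length(surv) > 0) {
        for (j in seq_len(nc)) {
          h <- Hbase[[j]][surv, t + 1L]
          if (CONDITIONS[j] %in% shift_targets) {
            w <- r_t * mults$eligible[surv]
            h <- (1 - w) * h + w * Hshift[[j]][surv, t + 1L]
          }
          p <- 1 - exp(-scales[j] * h * mults$inc[surv, j])
          if (any(p < 0 | p > 1)) stop("incidence probability outside [0,1]",
                                       call. = FALSE)
          new <- !active[surv, j] & (U_inc[surv, t + 1L, j] < p)
          if (any(new)) {
            w2 <- surv[new]
            active[w2, j] <- TRUE
            onset[w2, j] <- t
          }
        }
      }
      # (3) intervention cost accrual (expectation over reach)
      if (!is.null(scenario)) {
        cm <- scenario$cost_model
        year_cost <- switch(
          cm$basis,
          per_person_year = cm$unit_cost * length(idx) * r_t,
          per_eligible_person_year =
            cm$unit_cost * sum(mults$eligible[idx]) * r_t,
          per_incident_case = {
            tgt <- match(scenario$eligibility$target, CONDITIONS)
            cm$unit_cost * sum(onset[, tgt] == t, na.rm = TRUE) * r_t
          },
          stop("unknown cost basis: ", cm$basis, call. = FALSE))
        fixed <- if (is.null(cm$program_fixed)) 0 else cm$program_fixed
        cost <- cost + (year_cost + fixed) * disc[t + 1L]
      }
    }
  }

  # tallies: one row per (person, condition) episode
  ep <- which(active | !is.na(onset), arr.ind = TRUE)
  tallies <- data.frame(
    person = ep[, 1],
    condition = CONDITIONS[ep[, 2]],
    prevalent = prevalent[ep],
    onset_year = onset[ep],
    death_year = death_year[ep[, 1]],
    died_of_condition = !is.na(death_cause[ep[, 1]]) &
      death_cause[ep[, 1]] == ep[, 2],
    age_at_death = pop$age[ep[, 1]] + death_year[ep[, 1]],
    sex = pop$sex[ep[, 1]]
  )
  attr(tallies, "horizon") <- H

  d <- compute_dalys(tallies, daly_params, r)
  d0 <- compute_dalys(tallies, daly_params, 0)
  per10k <- 10000 / n
  inc_cnt <- vapply(seq_along(CONDITIONS), function(j)
    sum(!is.na(onset[, j]) & !prevalent[, j]), numeric(1))
  dth_cnt <- vapply(seq_along(CONDITIONS), function(j)
    sum(death_cause == j, na.rm = TRUE), numeric(1))

  res <- data.frame(
    condition = CONDITIONS,
    incidence = inc_cnt * per10k,
    mortality = dth_cnt * per10k,
    dalys = d$dalys * per10k,
    yld = d$yld * per10k,
    yll = d$yll * per10k,
    dalys_undiscounted = d0$dalys * per10k
  )
  tot <- data.frame(condition = "total", t(colSums(res[, -1])))
  names(tot) <- names(res)
  res <- rbind(res, tot)
  structure(res,
            class = c("ncd_result", "data.frame"),
            n = n, horizon = H, seed = seed,
            scenario = if (is.null(scenario)) "baseline" else scenario$who_id,
            other_cause_deaths = sum(death_cause == nc + 1L,
                                     na.rm = TRUE) * per10k,
            cost = cost * per10k)
}

#' Run the microsimulation
#'
#' Simulates every individual annually over the horizon with competing
#' risks and returns per-condition 10-year incidence, condition-attributed
#' deaths and discounted DALYs per 10,000, with a totals row that is the
#' exact sum of the condition rows. Deterministic for fixed seed; baseline
#' and scenario runs at the same seed share common random numbers.
#'
#' @param pop Population data frame (complete lab block).
#' @param models Named list of calibrated `ncd_condition_model`s.
#' @param daly_params An `ncd_daly_params`.
#' @param config An `ncd_sim_config`.
#' @param scenario Optional `ncd_intervention` applied during the run.
#' @return An `ncd_result` data frame (plus attributes `cost`,
#'   `other_cause_deaths`, `scenario`, `seed`). With `config$replicates > 1`
#'   the point estimates are replicate means and `*_lo`/`*_hi` columns give
#'   2.5/97.5 Monte-Carlo percentiles.
#' @export
run_simulation <- function(pop, models, daly_params = daly_parameters(),
                           config = sim_config(), scenario = NULL) {
  if (config$replicates == 1L)
    return(run_simulation_once(pop, models, daly_params, config, scenario))
  runs <- lapply(seq_len(config$replicates) - 1L, function(k)
    run_simulation_once(pop, models, daly_params, config, scenario,
                        seed = config$seed + k))
  base <- runs[[1]]
  num_cols <- setdiff(names(base), "condition")
  arr <- simplify2array(lapply(runs, function(x) as.matrix(x[num_cols])))
  out <- base
  out[num_cols] <- apply(arr, c(1, 2), mean)
  for (v in c("incidence", "mortality", "dalys")) {
    q <- apply(arr[, v, , drop = FALSE], 1, stats::quantile,
               probs = c(0.025, 0.975))
    out[[paste0(v, "_lo")]] <- q[1, ]
    out[[paste0(v, "_hi")]] <- q[2, ]
  }
  attr(out, "cost") <- mean(vapply(runs, attr, numeric(1), "cost"))
  out
}

#' Run baseline and scenario with common random numbers
#'
#' @inheritParams run_simulation
#' @param spec An `ncd_intervention` scenario.
#' @return List with `baseline`, `scenario` (both `ncd_result`) and `delta`
#'   (see [result_delta()]).
#' @export
simulate_scenario <- function(pop, models, daly_params = daly_parameters(),
                              config = sim_config(), spec) {
  baseline <- run_simulation(pop, models, daly_params, config, NULL)
  scen <- run_simulation(pop, models, daly_params, config, spec)
  list(baseline = baseline, scenario = scen,
       delta = result_delta(scen, baseline))
}
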