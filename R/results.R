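# Result containers and the panel aggregation layer.
#
# Simulation output and externally-configured burden panels share one
# container shape: five condition rows plus a totals row that is always the
# exact sum of the condition rows. Interval columns, when present, are
# reported sorted (lower, upper).

#' Load the baseline burden panel fixture
#'
#' Default calibration targets: ten-year incidence, condition-attributed
#' mortality and DALYs per 10,000 adults aged 40+, with 95% intervals, for
#' the five modeled conditions in the Gaza population.
#'
#' @param path CSV path (default: shipped fixture).
#' @return Data frame with one row per condition.
#' @export
baseline_burden_panel <- function(path = system.file(
                                    "extdata", "burden_baseline.csv",
                                    package = "ncdsim")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load the intervention effect panel fixture
#'
#' Per-intervention, per-condition changes from baseline (negative values
#' are reductions) in ten-year incidence, mortality and DALYs per 10,000,
#' used to configure scenarios to published effect sizes.
#'
#' @param who_id Optional intervention id filter (e.g. `"1.4"`).
#' @param path CSV path (default: shipped fixture).
#' @return Data frame of deltas.
#' @export
intervention_effect_panel <- function(who_id = NULL,
                                      path = system.file(
                                        "extdata", "intervention_effects.csv",
                                        package = "ncdsim")) {
  eff <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(who_id = "character"))
  if (!is.null(who_id)) {
    eff <- eff[eff$who_id %in% who_id, ]
    if (nrow(eff) == 0)
      stop("unknown intervention id: ", who_id, call. = FALSE)
  }
  eff
}

# append a totals row = exact column sums, sorting any *_lo/_hi pairs
add_totals_row <- function(df, label = "total") {
  stopifnot(setequal(df$condition, CONDITIONS))
  df <- df[match(CONDITIONS, df$condition), ]
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  tot <- df[1, , drop = FALSE]
  tot$condition <- label
  for (v in num) tot[[v]] <- sum(df[[v]])
  out <- rbind(df, tot)
  rownames(out) <- NULL
  # report intervals as (lower, upper) regardless of input order
  for (base in unique(sub("_(lo|hi)$", "", grep("_(lo|hi)$", num,
                                                value = TRUE)))) {
    lo <- paste0(base, "_lo")
    hi <- paste0(base, "_hi")
    if (all(c(lo, hi) %in% names(out))) {
      lower <- pmin(out[[lo]], out[[hi]])
      upper <- pmax(out[[lo]], out[[hi]])
      out[[lo]] <- lower
      out[[hi]] <- upper
    }
  }
  out
}

#' Aggregate a per-condition burden panel into a result table
#'
#' The aggregation layer used when scenarios are configured from published
#' per-condition values rather than simulated: validates the five condition
#' rows and appends a totals row equal to their exact sum (interval bounds
#' also sum and are reported sorted).
#'
#' @param panel Data frame with a `condition` column covering all of
#'   [conditions()] and numeric burden columns.
#' @return An `ncd_result` data frame with a `total` row.
#' @export
panel_result <- function(panel = baseline_burden_panel()) {
  out <- add_totals_row(panel)
  structure(out, class = c("ncd_result", "data.frame"), source = "panel")
}

#' Scenario deltas configured from the effect panel
#'
#' Returns the per-condition changes from baseline for one intervention,
#' with a totals row that is the exact sum of the condition rows and a
#' `dalys_averted` column (`-d_dalys`).
#'
#' @param who_id Intervention id (e.g. `"1.4"` for the smoking ban).
#' @param panel Effect panel, see [intervention_effect_panel()].
#' @return An `ncd_delta` data frame.
#' @export
panel_deltas <- function(who_id, panel = intervention_effect_panel(who_id)) {
  panel <- panel[panel$who_id == who_id, setdiff(names(panel), "who_id")]
  out <- add_totals_row(panel)
  out$dalys_averted <- -out$d_dalys
  structure(out, class = c("ncd_delta", "data.frame"), who_id = who_id)
}

#' Difference between a scenario and a baseline simulation result
#'
#' @param scenario,baseline `ncd_result` objects from [run_simulation()]
#'   under common random numbers.
#' @return An `ncd_delta` data frame (`d_*` columns equal scenario minus
#'   baseline exactly; `dalys_averted = -d_dalys`) with the scenario's
#'   discounted intervention cost as attribute `cost`.
#' @export
result_delta <- function(scenario, baseline) {
  stopifnot(identical(scenario$condition, baseline$condition))
  out <- data.frame(
    condition = scenario$condition,
    d_incidence = scenario$incidence - baseline$incidence,
    d_mortality = scenario$mortality - baseline$mortality,
    d_dalys = scenario$dalys - baseline$dalys
  )
  out$dalys_averted <- -out$d_dalys
  structure(out, class = c("ncd_delta", "data.frame"),
            who_id = attr(scenario, "scenario"),
            cost = attr(scenario, "cost"))
}

#' Totals row of a result or delta table
#' @param x An `ncd_result` or `ncd_delta`.
#' @return One-row data frame.
#' @export
result_totals <- function(x) {
  as.data.frame(x)[x$condition == "total", , drop = FALSE]
}

#' @export
print.ncd_result <- function(x, ...) {
  cat(sprintf("NCD simulation result (%s), per 10,000 over %s years\n",
              attr(x, "scenario") %||% "panel",
              attr(x, "horizon") %||% 10))
  print.data.frame(cbind(x[1], round(as.data.frame(x)[-1], 1)),
                   row.names = FALSE)
  if (!is.null(attr(x, "cost")) && attr(x, "cost") > 0)
    cat(sprintf("discounted intervention cost: $%.0f per 10,000\n",
                attr(x, "cost")))
  invisible(x)
}

#' @export
print.ncd_delta <- function(x, ...) {
  cat(sprintf("Change from baseline (%s)\n", attr(x, "who_id") %||% "?"))
  print.data.frame(cbind(x[1], round(as.data.frame(x)[-1], 1)),
                   row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result table as CSV
#' @param x Result or delta table.
#' @param path Output path.
#' @export
write_results <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
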