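# Configuration, end-to-end pipeline, manifest and serialization.

#' Default pipeline configuration
#'
#' @return Named list with the shipped defaults (also available as the
#'   YAML fixture `default_config.yaml`).
#' @export
default_config <- function() {
  yaml::read_yaml(system.file("extdata", "default_config.yaml",
                              package = "ncdsim"))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, injects defaults for omitted fields, and
#' validates every cross-field constraint before any computation; a schema
#' violation reports every failing field at once.
#'
#' @param path YAML file path.
#' @return Validated configuration list of class `ncd_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), cfg)
  # modifyList drops NULL-valued keys; keep the optional overrides slot
  if (!"overrides" %in% names(cfg$population))
    cfg$population["overrides"] <- list(NULL)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg Configuration list.
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$seed == round(cfg$seed), "seed must be an integer")
  chk(cfg$population$size >= 0, "population$size must be >= 0")
  chk(cfg$population$lab_observed_fraction >= 0 &&
        cfg$population$lab_observed_fraction <= 1,
      "population$lab_observed_fraction must lie in [0, 1]")
  chk(cfg$simulation$horizon_years >= 1,
      "simulation$horizon_years must be >= 1")
  chk(cfg$simulation$population_size >= 1,
      "simulation$population_size must be >= 1")
  chk(cfg$simulation$discount_rate >= 0,
      "simulation$discount_rate must be >= 0")
  chk(cfg$calibration$tolerance > 0, "calibration$tolerance must be > 0")
  chk(cfg$interventions$reach >= 0 && cfg$interventions$reach <= 1,
      "interventions$reach must lie in [0, 1]")
  lib_ids <- c("1.4", "2.11", "2.13", "3.1", "3.2", "6.2", "6.3", "6.4",
               "7.3")
  unknown <- setdiff(cfg$interventions$who_ids, lib_ids)
  chk(length(unknown) == 0,
      paste0("interventions$who_ids unknown: ",
             paste(unknown, collapse = ", ")))
  chk(cfg$psa$n_draws >= 1, "psa$n_draws must be >= 1")
  if (!is.null(cfg$population$overrides)) {
    ok <- tryCatch({
      do.call(population_spec, cfg$population$overrides)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) bad <- c(bad, ok)
  }
  if (length(bad) > 0)
    stop("invalid configuration:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  class(cfg) <- "ncd_config"
  cfg
}

#' Write a configuration as YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# order-independent structural hash of the analytic inputs (the output
# location is not an input, so it is excluded)
config_hash <- function(x) {
  x$output_dir <- NULL
  u <- unlist(x)
  s <- paste(names(u), as.character(u), sep = "=", collapse = ";")
  raw <- utf8ToInt(s)
  sprintf("%08x", sum(raw * (seq_along(raw) %% 97 + 1)) %% .Machine$integer.max)
}

stage_log <- function(stage, t0) {
  message(sprintf("[ncdsim] %-12s %6.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full pipeline
#'
#' Executes generate -> impute -> calibrate -> baseline run ->
#' per-intervention scenario runs (common random numbers) -> economics ->
#' optional PSA, and writes the results table, CE-plane table and run
#' manifest to `output_dir`. Deterministic for a fixed configuration: the
#' same config and seed produce bit-identical output files.
#'
#' @param cfg Configuration from [load_config()] / [default_config()].
#' @param output_dir Output directory (created if needed); `NULL` skips
#'   file output.
#' @return List with `population`, `models`, `baseline`, `scenarios`,
#'   `deltas`, `ce_table`, `psa`, `manifest`.
#' @export
run_pipeline <- function(cfg = validate_config(default_config()),
                         output_dir = cfg$output_dir) {
  cfg <- validate_config(unclass(cfg))
  t0 <- as.numeric(Sys.time())
  seed <- as.integer(cfg$seed)
  sub_seed <- function(k) (seed * 7919L + k) %% 2147483647L

  spec <- if (is.null(cfg$population$overrides)) default_population_spec()
  else do.call(population_spec, cfg$population$overrides)
  pop <- generate_population(spec, cfg$population$size, seed = sub_seed(1L))
  pop <- induce_lab_missingness(pop, cfg$population$lab_observed_fraction,
                                seed = sub_seed(2L))
  pop <- impute_missing(pop, seed = sub_seed(3L),
                        n_chains = cfg$population$imputation_chains)
  stage_log("generate", t0)

  # resample to the simulated cohort size
  set.seed(sub_seed(4L))
  idx <- sample.int(nrow(pop), cfg$simulation$population_size,
                    replace = TRUE)
  cohort <- pop[idx, ]
  rownames(cohort) <- NULL

  daly_params <- daly_parameters()
  config <- sim_config(cfg$simulation$horizon_years,
                       cfg$simulation$population_size,
                       cfg$simulation$discount_rate,
                       seed = sub_seed(5L),
                       replicates = cfg$simulation$replicates)
  targets <- default_calibration_targets()
  for (tg in names(targets)) targets[[tg]]$tolerance <-
    cfg$calibration$tolerance
  models <- calibrate_models(cohort, targets = targets,
                             daly_params = daly_params,
                             horizon = config$horizon_years)
  stage_log("calibrate", t0)

  baseline <- run_simulation(cohort, models, daly_params, config)
  stage_log("baseline", t0)

  lib <- intervention_library(reach = reach_curve(cfg$interventions$reach,
                                                  cfg$interventions$ramp))
  ids <- cfg$interventions$who_ids
  scenarios <- lapply(lib[ids], function(sp)
    run_simulation(cohort, models, daly_params, config, sp))
  deltas <- lapply(scenarios, result_delta, baseline = baseline)
  stage_log("scenarios", t0)

  ce <- cost_effectiveness_table(ids, library = lib,
                                 population = config$population_size,
                                 horizon = config$horizon_years,
                                 discount_rate = config$discount_rate)
  psa <- NULL
  if (isTRUE(cfg$psa$enabled)) {
    psa <- lapply(ids, function(id)
      run_psa(id, n_draws = cfg$psa$n_draws, seed = sub_seed(6L),
              library = lib, population = config$population_size,
              horizon = config$horizon_years,
              discount_rate = config$discount_rate))
    names(psa) <- ids
    stage_log("psa", t0)
  }

  manifest <- list(package_version = as.character(
                     utils::packageVersion("ncdsim")),
                   seed = seed, config_hash = config_hash(unclass(cfg)),
                   scenarios = ids,
                   fixtures = c("burden_baseline.csv",
                                "intervention_effects.csv",
                                "interventions.json",
                                "risk_coefficients.json",
                                "disability_weights.csv",
                                "life_table_synthetic.csv"))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- do.call(rbind, c(
      list(cbind(scenario = "baseline", as.data.frame(baseline),
                 d_incidence = NA_real_, d_mortality = NA_real_,
                 d_dalys = NA_real_)),
      lapply(ids, function(id) {
        s <- as.data.frame(scenarios[[id]])
        d <- as.data.frame(deltas[[id]])
        cbind(scenario = id, s, d[c("d_incidence", "d_mortality", "d_dalys")])
      })))
    utils::write.csv(tab, file.path(output_dir, "results.csv"),
                     row.names = FALSE)
    ce_plane_export(ce, file.path(output_dir, "ce_plane.csv"))
    if (!is.null(psa)) {
      psa_tab <- do.call(rbind, lapply(ids, function(id)
        cbind(who_id = id, as.data.frame(psa[[id]]))))
      utils::write.csv(psa_tab, file.path(output_dir, "psa.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  stage_log("done", t0)
  invisible(list(population = pop, models = models, baseline = baseline,
                 scenarios = scenarios, deltas = deltas, ce_table = ce,
                 psa = psa, manifest = manifest))
}
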