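# Shared fixtures, built in code at test time.

# small complete population (generator emits a full lab block)
small_pop <- function(n = 500, seed = 42) {
  generate_population(default_population_spec(), n, seed)
}

# cached heavyweight objects
.dp <- daly_parameters()
.models <- default_condition_models()

# condition models with everything switched off except `keep`
isolated_models <- function(keep = "cvd", scale = 2.2, case_fatality = 0) {
  m <- default_condition_models()
  for (cn in conditions()) {
    m[[cn]]$calibration_scale <- 0
    m[[cn]]$case_fatality <- 0
  }
  m[[keep]]$calibration_scale <- scale
  m[[keep]]$case_fatality <- case_fatality
  m
}

null_intervention <- function() {
  intervention_spec("null", mechanism = list(
    list(target = "cvd", channel = "incidence_rr", rr = 1)),
    cost_model = list(basis = "per_person_year", unit_cost = 0))
}
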