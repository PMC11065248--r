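test_that("the library holds the nine interventions with published costs", {
  lib <- intervention_library()
  expect_length(lib, 9)
  expect_setequal(names(lib), c("1.4", "2.11", "2.13", "3.1", "3.2",
                                "6.2", "6.3", "6.4", "7.3"))
  expect_equal(lib[["1.4"]]$cost_model$unit_cost, 0.20)
  expect_equal(lib[["2.11"]]$cost_model$unit_cost, 4)
  expect_equal(lib[["2.13"]]$cost_model$unit_cost, 0.30)
  expect_equal(lib[["3.1"]]$cost_model$unit_cost, 19)
  expect_equal(lib[["3.2"]]$cost_model$unit_cost, 110)
  expect_equal(lib[["6.2"]]$cost_model$unit_cost, 20)
  expect_equal(lib[["6.3"]]$cost_model$unit_cost, 14736)
  expect_equal(lib[["6.4"]]$cost_model$unit_cost, 1423)
  expect_equal(lib[["7.3"]]$cost_model$unit_cost, 24)
  for (sp in lib)
    for (m in sp$mechanism)
      if (m$channel %in% c("incidence_rr", "mortality_rr"))
        expect_gt(m$rr, 0)
})

test_that("reach curves follow their ramp conventions", {
  lin <- reach_curve(0.64, "linear_over_horizon")
  expect_equal(reach(lin, 9, 10), 0.64)     # final year reaches the target
  expect_equal(reach(lin, 4, 10), 0.32)     # midpoint of the scale-up
  imm <- reach_curve(0.64, "immediate")
  expect_true(all(reach(imm, 0:9, 10) == 0.64))
  fs <- reach_curve(0.64, "linear_from_start")
  expect_equal(reach(fs, 0, 10), 0.64 + 0.036)
  expect_equal(reach(fs, 9, 10), 1)
  zero <- reach_curve(0, "linear_over_horizon")
  expect_true(all(reach(zero, 0:9, 10) == 0))
  # nondecreasing within the horizon, every ramp
  for (cv in list(lin, imm, fs,
                  reach_curve(0.5, "custom", schedule = seq(0, 0.5, len = 10))))
    expect_false(is.unsorted(reach(cv, 0:9, 10)))
  expect_error(reach(lin, 10, 10), "out of range")
  expect_error(reach_curve(1.2), "\\[0, 1\\]")
  expect_error(reach_curve(0.5, "custom", schedule = c(0.5, 0.2)),
               "nondecreasing")
})

test_that("probability adjustment applies rate ratios on the hazard scale", {
  spec <- intervention_spec(
    "t", mechanism = list(list(target = "cvd", channel = "incidence_rr",
                               rr = 0.9)),
    cost_model = list(basis = "per_person_year", unit_cost = 2),
    reach = reach_curve(1, "immediate"))
  p <- c(cvd = 0.3, diabetes = 0.1)
  out <- apply_intervention(p, spec, year = 0, eligible = TRUE)
  # full reach: hazard multiplied by the rate ratio exactly
  expect_equal(-log(1 - out$probs[["cvd"]]), 0.9 * -log(1 - 0.3),
               tolerance = 1e-12)
  expect_equal(out$probs[["diabetes"]], 0.1)
  expect_equal(out$cost, 2)
  # reach 0.5: expectation-mode mixture multiplier 0.95
  spec$reach <- reach_curve(0.5, "immediate")
  out2 <- apply_intervention(p, spec, year = 0, eligible = TRUE)
  expect_equal(-log(1 - out2$probs[["cvd"]]), 0.95 * -log(1 - 0.3),
               tolerance = 1e-12)
  # null intervention: probabilities unchanged, zero cost
  nul <- null_intervention()
  out3 <- apply_intervention(p, nul, year = 0, eligible = TRUE)
  expect_identical(out3$probs, p)
  expect_equal(out3$cost, 0)
  expect_error(apply_intervention(c(cvd = 1.2), spec, 0), "\\[0, 1\\]")
})

test_that("a null intervention leaves the simulation bit-identical", {
  pop <- small_pop(800, seed = 61)
  models <- .models
  models$cvd$calibration_scale <- 2
  cfg <- sim_config(seed = 7)
  base <- run_simulation(pop, models, .dp, cfg)
  scen <- run_simulation(pop, models, .dp, cfg, null_intervention())
  d <- result_delta(scen, base)
  expect_true(all(d$d_incidence == 0))
  expect_true(all(d$d_mortality == 0))
  expect_true(all(d$d_dalys == 0))
  expect_equal(attr(scen, "cost"), 0)
})

test_that("mechanisms are local to their target condition", {
  pop <- small_pop(2000, seed = 62)
  # no fatality pathway for the target: effects cannot spill over
  models <- .models
  models$cvd$calibration_scale <- 2
  models$colorectal_cancer$calibration_scale <- 3
  models$colorectal_cancer$case_fatality <- 0
  spec <- intervention_spec(
    "t", mechanism = list(list(target = "colorectal_cancer",
                               channel = "incidence_rr", rr = 0.7)),
    cost_model = list(basis = "per_person_year", unit_cost = 0))
  cfg <- sim_config(seed = 8)
  base <- run_simulation(pop, models, .dp, cfg)
  scen <- run_simulation(pop, models, .dp, cfg, spec)
  d <- result_delta(scen, base)
  others <- d[!d$condition %in% c("colorectal_cancer", "total"), ]
  expect_true(all(others$d_incidence == 0))
  expect_true(all(others$d_mortality == 0))
  expect_true(all(others$d_dalys == 0))
  expect_lt(result_totals(d)$d_incidence, 0)
})

test_that("eligibility predicates are total and correct", {
  pop <- small_pop(300, seed = 63)
  lib <- intervention_library()
  mask <- ncdsim:::eligibility_mask(lib[["6.2"]]$eligibility, pop)
  expect_identical(mask, pop$sex == "female" & pop$age >= 50 & pop$age <= 69)
  mask2 <- ncdsim:::eligibility_mask(lib[["7.3"]]$eligibility, pop)
  expect_identical(mask2, pop$dx_asthma_copd)
  expect_length(ncdsim:::eligibility_mask(lib[["1.4"]]$eligibility, pop),
                nrow(pop))
})

test_that("factor shifts blend hazards of the shifted cohort", {
  pop <- small_pop(1500, seed = 64)
  models <- isolated_models("cvd", scale = 2, case_fatality = 0)
  spec <- intervention_spec(
    "t", mechanism = list(list(target = "cvd", channel = "factor_shift",
                               field = "sbp", magnitude = -20)),
    cost_model = list(basis = "per_person_year", unit_cost = 0),
    reach = reach_curve(1, "immediate"))
  cfg <- sim_config(seed = 9)
  base <- run_simulation(pop, models, .dp, cfg)
  scen <- run_simulation(pop, models, .dp, cfg, spec)
  expect_lt(result_totals(result_delta(scen, base))$d_incidence, 0)
})
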