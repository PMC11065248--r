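test_that("calibrating to a model's own rates is a fixed point", {
  pop <- small_pop(500, seed = 31)
  er <- expected_rates(pop, .models, .dp)
  tg <- calibration_target("cvd", er$incidence[["cvd"]], er$deaths[["cvd"]])
  cal <- calibrate(pop, .models$cvd, tg, .dp, models_context = .models)
  expect_equal(cal$calibration_scale, 1, tolerance = 0.05)
  expect_equal(cal$cf_scale, 1, tolerance = 0.05)
})

test_that("a planted hazard scale is recovered within 2%", {
  pop <- small_pop(2000, seed = 42)
  planted <- .models
  planted$cvd$calibration_scale <- 1.7
  er <- expected_rates(pop, planted, .dp)
  tg <- calibration_target("cvd", er$incidence[["cvd"]], er$deaths[["cvd"]],
                           tolerance = 0.005)
  cal <- calibrate(pop, .models$cvd, tg, .dp, models_context = .models)
  expect_lt(abs(cal$calibration_scale - 1.7) / 1.7, 0.02)
  achieved <- attr(cal, "achieved")
  expect_equal(achieved$incidence[["cvd"]], tg$incidence, tolerance = 0.01)
  expect_equal(achieved$deaths[["cvd"]], tg$mortality, tolerance = 0.01)
})

test_that("the scale is monotone in the target and matches a root-finding oracle", {
  pop <- small_pop(200, seed = 5)
  f <- function(s) {
    m <- .models
    m$cvd$calibration_scale <- s
    expected_rates(pop, m, .dp)$incidence[["cvd"]]
  }
  t1 <- f(1.3)
  cal1 <- calibrate(pop, .models$cvd,
                    calibration_target("cvd", t1, 50, tolerance = 0.005),
                    .dp, models_context = .models)
  cal2 <- calibrate(pop, .models$cvd,
                    calibration_target("cvd", 2 * t1, 50, tolerance = 0.005),
                    .dp, models_context = .models)
  expect_gt(cal2$calibration_scale, cal1$calibration_scale)
  oracle <- stats::uniroot(function(s) f(s) - t1, c(0.1, 10),
                           tol = 1e-6)$root
  expect_equal(cal1$calibration_scale, oracle, tolerance = 0.01)
})

test_that("unreachable targets raise calibration errors", {
  pop <- small_pop(200, seed = 6)
  expect_error(
    calibrate(pop, .models$cvd,
              calibration_target("cvd", 9990, 50), .dp,
              models_context = .models),
    "unreachable")
  expect_error(calibration_target("cvd", 100, 10001))
})

test_that("recalibrating a calibrated model barely moves the scale", {
  pop <- small_pop(800, seed = 33)
  tg <- calibration_target("cvd", 3417, 163)
  cal <- calibrate(pop, .models$cvd, tg, .dp, models_context = .models)
  recal <- calibrate(pop, cal, tg, .dp, models_context = .models)
  expect_equal(recal$calibration_scale, cal$calibration_scale,
               tolerance = 0.05)
})

test_that("full-panel calibration reproduces the burden targets", {
  pop <- small_pop(2000, seed = 34)
  cal <- calibrate_models(pop, daly_params = .dp)
  er <- expected_rates(pop, cal, .dp)
  targets <- default_calibration_targets()
  for (cn in conditions()) {
    expect_lt(abs(er$incidence[[cn]] - targets[[cn]]$incidence) /
                targets[[cn]]$incidence, 0.025)
    expect_lt(abs(er$deaths[[cn]] - targets[[cn]]$mortality) /
                targets[[cn]]$mortality, 0.025)
  }
  # stochastic engine agrees with the mean-field expectation
  res <- run_simulation(pop, cal, .dp, sim_config(seed = 2, replicates = 3))
  expect_equal(res$incidence[res$condition == "cvd"], 3417,
               tolerance = 0.06)
})

test_that("the calibrated baseline lands inside the published intervals", {
  # per condition, simulated incidence and mortality per 10,000 fall within
  # the target panel's 95% intervals in at least 4 of 5 replicate seeds
  pop <- small_pop(4576, seed = 1)
  set.seed(99)
  cohort <- pop[sample.int(nrow(pop), 10000, replace = TRUE), ]
  rownames(cohort) <- NULL
  models <- calibrate_models(cohort, daly_params = .dp)
  panel <- baseline_burden_panel()
  ok_inc <- ok_mort <- matrix(FALSE, 5, 5)
  for (s in 1:5) {
    res <- run_simulation(cohort, models, .dp, sim_config(seed = s))
    body <- res[res$condition != "total", ]
    ok_inc[s, ] <- body$incidence >= panel$incidence_lo &
      body$incidence <= panel$incidence_hi
    ok_mort[s, ] <- body$mortality >= panel$mortality_lo &
      body$mortality <= panel$mortality_hi
  }
  expect_true(all(colSums(ok_inc) >= 4))
  expect_true(all(colSums(ok_mort) >= 4))
})
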