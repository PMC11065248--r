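test_that("discounted annuity matches its closed form", {
  expect_equal(discounted_annuity(1, 0.07), 1)
  expect_equal(discounted_annuity(1, 0), 1)
  expect_equal(discounted_annuity(10, 0), 10)
  expect_equal(discounted_annuity(10, 0.03), 8.7861, tolerance = 1e-4)
  # fractional years: floor annuity plus discounted fraction
  expect_equal(discounted_annuity(2.5, 0.03),
               1 + 1 / 1.03 + 0.5 / 1.03^2, tolerance = 1e-12)
  expect_error(discounted_annuity(-1, 0.03))
})

test_that("DALY accounting matches the closed-form annuity contract", {
  dw <- c(cvd = 0.2, diabetes = 0.1, asthma_copd = 0.1, breast_cancer = 0.1,
          colorectal_cancer = 0.1)
  dp <- daly_parameters(disability_weights = dw)
  tallies <- data.frame(person = 1L, condition = "cvd", prevalent = FALSE,
                        onset_year = 0L, death_year = NA_integer_,
                        died_of_condition = FALSE, age_at_death = NA_real_,
                        sex = "male")
  attr(tallies, "horizon") <- 10L
  d <- compute_dalys(tallies, dp, 0.03)
  expect_equal(d$dalys[d$condition == "cvd"], 0.2 * 8.786109,
               tolerance = 1e-5)
  # zero-rate limit: plain person-year sums
  d0 <- compute_dalys(tallies, dp, 0)
  expect_equal(d0$dalys[d0$condition == "cvd"], 0.2 * 10)
  # empty tallies
  empty <- tallies[0, ]
  attr(empty, "horizon") <- 10L
  expect_true(all(compute_dalys(empty, dp, 0.03)$dalys == 0))
  # negative years are a hard error
  bad <- tallies
  bad$onset_year <- -1L
  expect_error(compute_dalys(bad, dp, 0.03), "negative")
})

test_that("competing-risk cause allocation matches the closed form", {
  # two prevalent conditions with annual probability 0.5 each, one cycle:
  # allocation fractions must match h_i / sum(h) * (1 - exp(-sum(h)))
  n <- 200000
  pop <- small_pop(2000, seed = 51)
  pop <- pop[rep(seq_len(2000), length.out = n), ]
  pop$age <- 40L  # minimise other-cause mortality
  pop$sex <- "male"
  pop$dx_diabetes <- TRUE
  pop$dx_asthma_copd <- TRUE
  rownames(pop) <- NULL
  h <- -log(1 - 0.5)
  models <- isolated_models("cvd", scale = 0)
  models$diabetes$case_fatality <- h
  models$asthma_copd$case_fatality <- h
  res <- run_simulation(pop, models, .dp,
                        sim_config(horizon_years = 1, seed = 8))
  h_oc <- ncdsim:::other_cause_hazard(.dp, 40, "male")
  H <- 2 * h + h_oc
  expected_frac <- h / H * (1 - exp(-H))
  se3 <- 3 * sqrt(expected_frac * (1 - expected_frac) / n) * 10000
  for (cn in c("diabetes", "asthma_copd"))
    expect_lt(abs(res$mortality[res$condition == cn] -
                    expected_frac * 10000), se3)
  # total death probability matches 1 - exp(-sum of hazards)
  total_dead <- sum(res$mortality[res$condition != "total"]) +
    attr(res, "other_cause_deaths")
  p_dead <- 1 - exp(-H)
  expect_lt(abs(total_dead - p_dead * 10000),
            3 * sqrt(p_dead * (1 - p_dead) / n) * 10000)
})

test_that("a null-risk model produces zero incidence, deaths and DALYs", {
  pop <- small_pop(500, seed = 52)
  # no prevalent disease either, so no disability accrues from year 0
  pop$dx_diabetes <- pop$dx_asthma_copd <- FALSE
  models <- isolated_models("cvd", scale = 0)
  res <- run_simulation(pop, models, .dp, sim_config(seed = 3))
  body <- res[res$condition != "total", ]
  expect_true(all(body$incidence == 0))
  expect_true(all(body$mortality == 0))
  expect_true(all(body$dalys == 0))
  # other-cause deaths still occur
  expect_gt(attr(res, "other_cause_deaths"), 0)
})

test_that("runs are deterministic and totals rows are exact sums", {
  pop <- small_pop(800, seed = 53)
  models <- .models
  models$cvd$calibration_scale <- 2
  cfg <- sim_config(seed = 4)
  a <- run_simulation(pop, models, .dp, cfg)
  b <- run_simulation(pop, models, .dp, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  body <- a[a$condition != "total", ]
  tot <- a[a$condition == "total", ]
  for (v in c("incidence", "mortality", "dalys", "yld", "yll"))
    expect_identical(tot[[v]], sum(body[[v]]))
  expect_true(all(a$dalys >= 0))
  # dead individuals accrue exactly one cause: counts are conserved
  expect_lte(sum(body$mortality) + attr(a, "other_cause_deaths"), 10000)
})

test_that("raising a disability weight cannot decrease total DALYs", {
  pop <- small_pop(600, seed = 54)
  models <- .models
  models$cvd$calibration_scale <- 2
  cfg <- sim_config(seed = 5)
  low <- daly_parameters(disability_weights = c(
    cvd = 0.05, diabetes = 0.07, asthma_copd = 0.19, breast_cancer = 0.29,
    colorectal_cancer = 0.29))
  high <- daly_parameters(disability_weights = c(
    cvd = 0.30, diabetes = 0.07, asthma_copd = 0.19, breast_cancer = 0.29,
    colorectal_cancer = 0.29))
  d_low <- run_simulation(pop, models, low, cfg)
  d_high <- run_simulation(pop, models, high, cfg)
  expect_gte(d_high$dalys[d_high$condition == "total"],
             d_low$dalys[d_low$condition == "total"])
})

test_that("replicate runs produce Monte-Carlo intervals around the mean", {
  pop <- small_pop(400, seed = 55)
  models <- .models
  models$cvd$calibration_scale <- 2
  res <- run_simulation(pop, models, .dp, sim_config(seed = 6,
                                                     replicates = 5))
  expect_true(all(c("incidence_lo", "incidence_hi") %in% names(res)))
  expect_true(all(res$incidence_lo <= res$incidence + 1e-9))
  expect_true(all(res$incidence_hi >= res$incidence - 1e-9))
})

test_that("scenarios referencing unknown conditions are rejected", {
  pop <- small_pop(100, seed = 56)
  bad <- null_intervention()
  bad$mechanism[[1]]$target <- "gout"
  expect_error(run_simulation(pop, .models, .dp, sim_config(seed = 1), bad),
               "unknown condition")
})
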