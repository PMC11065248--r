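test_that("annual risks are probabilities for any admissible profile", {
  for (seed in 1:5) {
    pop <- small_pop(2000, seed)
    for (m in .models) {
      p <- annual_risk(m, pop)
      expect_true(all(p >= 0 & p <= 1))
      expect_true(all(is.finite(p)))
    }
  }
})

test_that("doubling the calibration scale doubles the cumulative hazard", {
  pop <- small_pop(400, seed = 21)
  for (m in .models) {
    m1 <- m
    m1$calibration_scale <- 0.8
    m2 <- m
    m2$calibration_scale <- 1.6
    expect_equal(-log(1 - annual_risk(m2, pop)),
                 2 * -log(1 - annual_risk(m1, pop)), tolerance = 1e-12)
  }
  # degenerate scale: zero risk for any profile
  m0 <- .models$cvd
  m0$calibration_scale <- 0
  expect_true(all(annual_risk(m0, pop) == 0))
})

test_that("the cardiovascular score averages the three country risks", {
  pop <- small_pop(300, seed = 22)
  cf <- .models$cvd$coefficients
  # independent oracle: compute each single-country 10-year risk directly
  lp <- cf$b_age * (pop$age - 60) + cf$b_male * (pop$sex == "male") +
    cf$b_sbp * (pop$sbp - 120) / 10 + cf$b_tc * (pop$total_chol - 200) / 40 +
    cf$b_smoke * pop$smoker + cf$b_dm * pop$dx_diabetes
  p10_by_country <- sapply(unlist(cf$country_h0),
                           function(h0) 1 - exp(-h0 * exp(lp)))
  h_expected <- -log(1 - rowMeans(p10_by_country)) / 10
  expect_equal(base_hazard(.models$cvd, pop), h_expected, tolerance = 1e-10)
})

test_that("FINDRISC points follow the category table and are monotone", {
  prof <- function(age, bmi, rx = FALSE)
    data.frame(age = age, bmi = bmi, rx_hypertension = rx)
  expect_identical(findrisc_points(prof(40, 22)), 0L)
  # BMI band carries its own and the waist points (documented mapping)
  expect_identical(findrisc_points(prof(40, 27)), 1L + 3L)
  expect_identical(findrisc_points(prof(40, 32)), 3L + 4L)
  expect_identical(findrisc_points(prof(50, 22)), 2L)
  expect_identical(findrisc_points(prof(60, 22)), 3L)
  expect_identical(findrisc_points(prof(70, 22)), 4L)
  expect_identical(findrisc_points(prof(40, 22, rx = TRUE)), 2L)
  # strictly increasing from BMI 24 to 32, all else fixed
  expect_gt(findrisc_points(prof(55, 32)), findrisc_points(prof(55, 24)))
  # risk nondecreasing in age band
  p_young <- annual_risk(.models$diabetes, prof(44, 28))
  p_old <- annual_risk(.models$diabetes, prof(66, 28))
  expect_gt(p_old, p_young)
})

test_that("sex restriction and smoke-exposure ratios behave", {
  pop <- small_pop(300, seed = 23)
  males <- pop[pop$sex == "male", ]
  expect_true(all(annual_risk(.models$breast_cancer, males) == 0))
  females <- pop[pop$sex == "female", ]
  expect_true(all(annual_risk(.models$breast_cancer, females) > 0))

  ns <- data.frame(smoker = FALSE)
  sm <- data.frame(smoker = TRUE)
  expect_equal(smoke_exposure_rr(ns), 1)
  expect_equal(smoke_exposure_rr(sm, rr_active = 1.5), 1.5)
  expect_equal(smoke_exposure_rr(sm, list(secondhand_exposed = TRUE),
                                 rr_active = 1.5, rr_secondhand = 1.2),
               1.5 * 1.2)
  expect_error(smoke_exposure_rr(sm, rr_active = -1), "> 0")
})

test_that("families ignore fields they do not use", {
  pop <- small_pop(200, seed = 24)
  pert <- pop
  pert$total_chol <- pop$total_chol + 40
  expect_identical(annual_risk(.models$diabetes, pert),
                   annual_risk(.models$diabetes, pop))
  pert2 <- pop
  pert2$bmi <- pop$bmi + 3
  expect_identical(annual_risk(.models$cvd, pert2),
                   annual_risk(.models$cvd, pop))
})

test_that("missing required inputs raise explicit errors", {
  pop <- small_pop(50, seed = 25)
  expect_error(annual_risk(.models$cvd, pop[setdiff(names(pop), "sbp")]),
               "sbp")
  pop$total_chol[3] <- NA
  expect_error(annual_risk(.models$cvd, pop), "total_chol")
})
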