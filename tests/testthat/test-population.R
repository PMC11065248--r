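test_that("generation is deterministic and the empty case works", {
  a <- generate_population(n = 300, seed = 9)
  b <- generate_population(n = 300, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_population(n = 300, seed = 10)))
  empty <- generate_population(n = 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("id", "age", "sex", "sbp", "bmi", "hba1c") %in%
                    names(empty)))
})

test_that("records satisfy the individual-level invariants", {
  pop <- small_pop(2000, seed = 7)
  expect_true(all(pop$age >= 40 & pop$age <= 80))
  expect_true(all(pop$age == round(pop$age)))
  expect_true(all(pop$sbp >= 70 & pop$sbp <= 260))
  expect_true(all(pop$bmi >= 12 & pop$bmi <= 70))
  expect_true(all(pop$hba1c >= 4 & pop$hba1c <= 20))
  # medication implies diagnosis
  expect_true(all(!pop$rx_diabetes | pop$dx_diabetes))
  expect_true(all(!pop$rx_hypertension | pop$dx_hypertension))
  expect_true(all(!pop$rx_statin | pop$dx_dyslipidemia))
  # generator emits a fully populated lab block
  expect_false(anyNA(pop[c("total_chol", "triglycerides", "ldl", "hdl",
                           "creatinine", "hba1c")]))
})

test_that("survey marginals are recovered at full sample size", {
  pop <- generate_population(n = 4576, seed = 3)
  se <- function(p) sqrt(p * (1 - p) / 4576)
  expect_lt(abs(mean(pop$sex == "female") - 0.540), 3 * se(0.540))
  male <- pop[pop$sex == "male", ]
  expect_lt(abs(mean(male$smoker) - 0.609),
            3 * sqrt(0.609 * 0.391 / nrow(male)))
  # sex-conditional structure: smoking is concentrated among men
  female <- pop[pop$sex == "female", ]
  expect_gt(mean(male$smoker) - mean(female$smoker), 0.5)
  # hba1c is conditioned on diabetes diagnosis
  expect_gt(mean(pop$hba1c[pop$dx_diabetes]) -
              mean(pop$hba1c[!pop$dx_diabetes]), 3)
})

test_that("lab missingness hits the expected counts and edge cases", {
  pop <- generate_population(n = 4576, seed = 5)
  expect_identical(induce_lab_missingness(pop, 1, seed = 1), pop)
  p2 <- induce_lab_missingness(pop, 1938 / 4576, seed = 1)
  n_obs <- sum(!is.na(p2$hba1c))
  expect_lt(abs(n_obs - 1938), 3 * sqrt(4576 * (1938 / 4576) * (1 - 1938 / 4576)))
  # lab block is removed jointly
  expect_identical(is.na(p2$hba1c), is.na(p2$total_chol))
  big <- generate_population(n = 10000, seed = 6)
  b2 <- induce_lab_missingness(big, 0.5, seed = 2)
  expect_lt(abs(sum(!is.na(b2$ldl)) - 5000), 3 * sqrt(10000 * 0.25))
  expect_error(induce_lab_missingness(pop, 1.2), "\\[0, 1\\]")
})

test_that("invalid specifications are rejected naming the field", {
  expect_error(population_spec(female_fraction = 1.4), "female_fraction")
  expect_error(population_spec(male = list(prev = c(
    refugee = 0.685, dx_diabetes = 1.2, dx_hypertension = 0.379,
    dx_dyslipidemia = 0.214, dx_asthma_copd = 0.101, smoker = 0.609,
    waterpipe = 0.145))), "dx_diabetes")
  bad_R <- default_dependence()
  bad_R[1, 2] <- bad_R[2, 1] <- 2
  expect_error(population_spec(dependence = bad_R), "positive semidefinite")
  asym <- default_dependence()
  asym[1, 2] <- 0.9
  expect_error(population_spec(dependence = asym), "symmetric")
})

test_that("population round-trips through CSV", {
  pop <- induce_lab_missingness(small_pop(200, seed = 1), 0.5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(back$age, pop$age)
  expect_equal(back$smoker, pop$smoker)
  expect_equal(is.na(back$hba1c), is.na(pop$hba1c))
  expect_equal(back$sbp, pop$sbp, tolerance = 1e-8)
})
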