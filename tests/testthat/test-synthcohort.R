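test_that("configs are validated before any sampling", {
  expect_error(cohort_sim_config(n = 0), "n must be")
  expect_error(cohort_sim_config(potassium = list(means = c(4, 3, 5),
                                                  sds = c(0.3, 0.3, 0.3),
                                                  weights = c(0.5, 0.4, 0.4))),
               "sum to 1")
  expect_error(cohort_sim_config(sbp = list(mean = 175, sd = 0)), "positive")
  expect_error(cohort_sim_config(p_ivh = 1.2), "probability")
  expect_error(ellipsoid_sim_config(slice_thickness = 35), "smallest axis")
  expect_error(ellipsoid_sim_config(shrinkage_factor = 0.5), "shrinkage_factor")
  expect_error(ellipsoid_sim_config(axes = c(40, -1, 50)), "positive")
})

test_that("the same seed reproduces the cohort exactly", {
  a <- generate_cohort(cohort_sim_config(n = 200, seed = 10))
  b <- generate_cohort(cohort_sim_config(n = 200, seed = 10))
  expect_identical(a, b)
  c <- generate_cohort(cohort_sim_config(n = 200, seed = 11))
  expect_false(identical(a, c))
})

test_that("covariate moments match the sampled (truncated) distributions", {
  n <- 60000
  co <- generate_cohort(cohort_sim_config(n = n, seed = 21))
  # truncated-normal mean for age on [18, 100]
  al <- (18 - 67) / 13; be <- (100 - 67) / 13
  age_mean <- 67 + 13 * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
  expect_lt(abs(mean(co$age_years) - age_mean), 3 * 13 / sqrt(n))
  expect_lt(abs(mean(co$sbp_mmhg) - 175), 3 * 34 / sqrt(n))
  # glucose lognormal is untruncated: mean is exactly the target
  expect_lt(abs(mean(co$glucose_mmol_l) - 8.1), 3 * 3.9 / sqrt(n))
  # relative volume: numerically integrated mean of the truncated lognormal
  s2 <- log(1 + (0.027 / 0.027)^2)
  mu <- log(0.027) - s2 / 2
  Z <- plnorm(0.3, mu, sqrt(s2))
  rv_mean <- integrate(function(x) x * dlnorm(x, mu, sqrt(s2)) / Z, 0, 0.3,
                       rel.tol = 1e-10)$value
  rel <- co$total_vol_cm3 / co$icv_cm3
  expect_lt(abs(mean(rel) - rv_mean), 3 * 0.027 / sqrt(n))
  # potassium mixture mean 0.8*4.1 + 0.1*3.1 + 0.1*5.4
  expect_lt(abs(mean(co$potassium_mmol_l) - 4.13), 3 * sd(co$potassium_mmol_l) / sqrt(n))
  expect_lt(abs(mean(co$ivh_present) - 0.416), 3 * sqrt(0.416 * 0.584 / n))
  # platelets truncated below 10
  zl <- (10 - 221) / 84
  plt_mean <- 221 + 84 * dnorm(zl) / (1 - pnorm(zl))
  expect_lt(abs(mean(co$platelets_1e9_l) - plt_mean), 3 * 84 / sqrt(n))
})

test_that("the death rate agrees with an independent Monte-Carlo probability mean", {
  co <- generate_cohort(cohort_sim_config(n = 50000, seed = 31))
  oracle <- generate_cohort(cohort_sim_config(n = 50000, seed = 32))
  pr_mean <- mean(score_cohort(oracle)$pr)
  expect_lt(abs(mean(co$death30) - pr_mean), 0.01)
})

test_that("an extreme linear predictor drives the death rate to its limit", {
  b <- suspekt_coefficients(b_glucose = 0, b_relvol = 0, b_sbp = 0, b_ivh = 0,
                            b_potassium = 0, b_potassium_sq = 0, b_age = 0,
                            constant = -10)
  co <- generate_cohort(cohort_sim_config(n = 10000, seed = 4, coefficients = b))
  expect_lt(mean(co$death30), 0.001)
})

test_that("simulated nonsurvivors show the adverse covariate profile", {
  co <- generate_cohort(cohort_sim_config(n = 20000, seed = 8))
  dead <- co$death30 == 1
  rel <- co$total_vol_cm3 / co$icv_cm3
  expect_gt(mean(co$glucose_mmol_l[dead]), mean(co$glucose_mmol_l[!dead]))
  expect_gt(mean(rel[dead]), mean(rel[!dead]))
  expect_gt(mean(co$sbp_mmhg[dead]), mean(co$sbp_mmhg[!dead]))
  expect_gt(mean(co$age_years[dead]), mean(co$age_years[!dead]))
  expect_gt(mean(co$ivh_present[dead]), mean(co$ivh_present[!dead]))
  # potassium separates in spread, not in mean (hypo/hyper mixture)
  expect_gt(sd(co$potassium_mmol_l[dead]), sd(co$potassium_mmol_l[!dead]))
  # survivors resorb on average, nonsurvivors expand
  gi <- suppressMessages(cohort_growth_index(co))$growth_index
  expect_lt(mean(gi[!dead], na.rm = TRUE), 0)
  expect_gt(mean(gi[dead], na.rm = TRUE), 0)
})

test_that("generated cohorts pass schema validation and round-trip", {
  co <- generate_cohort(cohort_sim_config(n = 30, seed = 12))
  expect_identical(names(co), cohort_schema())
  expect_silent(validate_cohort(co))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_equal(read_cohort(path), co, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ellipsoid slicing recovers the C extent exactly without noise", {
  for (s in c(1, 0.85, 0.75)) {
    st <- generate_slice_stack(ellipsoid_sim_config(shrinkage_factor = s))
    expect_equal(cadaver_c_axis(st), 50, tolerance = 1e-9)
  }
})

test_that("shrinkage leaves the recovered volume unchanged", {
  v1 <- cadaver_abc2(generate_slice_stack(ellipsoid_sim_config(shrinkage_factor = 1)))
  v085 <- cadaver_abc2(generate_slice_stack(ellipsoid_sim_config(shrinkage_factor = 0.85)))
  expect_lt(abs(v085 - v1) / v1, 0.02)
})

test_that("noisy stacks stay near the noise-free volume", {
  set.seed(2)
  st <- generate_slice_stack(ellipsoid_sim_config(
    slice_thickness = 5, thickness_jitter_sd = 0.2,
    measurement_noise_sd = 0.8, seed = 2))
  expect_lt(abs(cadaver_abc2(st) - 30) / 30, 0.12)
})
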