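test_that("partial products reproduce the published example column", {
  printed <- suspekt_worked_example()$bx
  bx <- partial_products(example_patient())
  # the published x values are rounded means, so agreement is to ~0.02
  expect_true(all(abs(bx - printed) < 0.02))
  expect_named(bx, c("glucose", "relvol", "sbp", "ivh", "potassium",
                     "potassium_sq", "age", "constant"))
})

test_that("partial products are linear per factor and validate input", {
  x <- example_patient()
  b <- suspekt_coefficients()
  zero <- partial_products(list(glucose = 0, rel_total_volume = 0, sbp = 0,
                                ivh = 0, potassium = 1e-12, age = 0), b)
  expect_equal(unname(zero[c(1:4, 7)]), rep(0, 5))
  expect_equal(unname(zero["constant"]), unclass(b)[["constant"]])
  b2 <- suspekt_coefficients(b_age = 2 * unclass(b)[["age"]])
  bx1 <- partial_products(x, b); bx2 <- partial_products(x, b2)
  expect_equal(bx2[["age"]], 2 * bx1[["age"]])
  expect_equal(bx2[-7], bx1[-7])
  expect_error(partial_products(x[-2]), "rel_total_volume")
  x$potassium <- -1
  expect_error(partial_products(x), "potassium")
})

test_that("the linear predictor is the exact order-invariant sum", {
  printed <- suspekt_worked_example()$bx
  expect_equal(round(linear_predictor(printed), 4), -0.2749)
  expect_equal(linear_predictor(rep(0, 8)), 0)
  set.seed(3)
  for (i in 1:5) expect_equal(linear_predictor(sample(printed)),
                              linear_predictor(printed))
  expect_error(linear_predictor(printed[-1]), "8")
})

test_that("the logistic transform is stable, increasing and symmetric", {
  expect_equal(score_probability(0), 0.5)
  expect_equal(score_probability(-0.274882), 0.431706, tolerance = 1e-5)
  s <- seq(-700, 700, length.out = 401)
  p <- score_probability(s)
  expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
  expect_equal(score_probability(s) + score_probability(-s), rep(1, length(s)))
  expect_equal(score_probability(s), plogis(s), tolerance = 1e-12)
})

test_that("band lookup brackets the probability with half-open intervals", {
  tab <- suspekt_band_table()
  b <- assign_band(0.432, tab)
  expect_equal(b$lower_label, "50th")
  expect_equal(b$upper_label, "60th")
  expect_equal(b$lower_percentile, 50)
  # the minimum itself is inside the bottom band (lower-inclusive)
  bmin <- assign_band(0.036732, tab)
  expect_equal(bmin$lower_label, "minimum")
  expect_equal(bmin$upper_label, "10th")
  expect_true(assign_band(0.02, tab)$below_min)
  expect_equal(assign_band(0.999965, tab)$lower_label, "90th")
  expect_false(assign_band(0.999965, tab)$above_max)
  expect_true(assign_band(0.9999999, tab)$above_max)
  expect_error(suspekt_band_table(rev(as.numeric(tab))), "non-decreasing")
})

test_that("band anchors bracket every probability they assign", {
  set.seed(12)
  p <- runif(60, 0.01, 0.99)
  tab <- build_band_table(p)
  for (pr in sample(p, 20)) {
    b <- assign_band(pr, tab)
    expect_false(b$below_min)
    expect_true(b$lower <= pr)
    expect_true(pr < b$upper || (pr == max(p) && !b$above_max))
  }
  # every anchor value lands in the band it opens
  a <- as.numeric(tab)
  for (k in 1:10) expect_equal(assign_band(a[k], tab)$lower, a[k])
})

test_that("band tables derive from samples by nearest rank or interpolation", {
  p <- seq(0.005, 0.995, by = 0.01)  # 100 equally spaced values
  tab <- build_band_table(p)
  a <- as.numeric(tab)
  # nearest-rank oracle: sorted[ceiling(q*n)]
  expect_equal(a, c(min(p), sort(p)[ceiling(seq(0.1, 0.9, 0.1) * 100)], max(p)))
  expect_lt(abs(a[2] - 0.1), 0.01 + 1e-12)  # 10th anchor within one grid step
  lin <- build_band_table(p, method = "linear")
  expect_equal(as.numeric(lin)[2], unname(quantile(p, 0.1)), tolerance = 1e-12)
  expect_equal(as.numeric(build_band_table(rep(0.3, 15))), rep(0.3, 11))
  expect_error(build_band_table(runif(9, 0.2, 0.8)), "at least 10")
  expect_error(build_band_table(c(rep(0.4, 10), 1.2)), "strictly in")
})

test_that("scoring composes the pieces and is monotone in each positive factor", {
  s <- score_patient(example_patient())
  expect_equal(s$sbx, linear_predictor(s$bx))
  expect_equal(s$pr, score_probability(s$sbx))
  # the published x are rounded means, so pr agrees with the published
  # 0.431706 only to a few thousandths
  expect_lt(abs(s$pr - 0.431706), 0.005)
  expect_equal(s$band$lower_label, "50th")
  # one unit of glucose moves the linear predictor by exactly its coefficient
  x2 <- example_patient(); x2$glucose <- x2$glucose + 1
  expect_equal(score_patient(x2)$sbx - s$sbx, 0.105504, tolerance = 1e-10)
  for (f in c("glucose", "rel_total_volume", "sbp", "ivh", "age")) {
    up <- example_patient()
    up[[f]] <- up[[f]] * 1.01 + 0.01
    expect_gt(score_patient(up)$pr, s$pr)
  }
})

test_that("risk is U-shaped in potassium with the vertex at -b1/(2*b2)", {
  kk <- seq(2.5, 6.0, by = 0.01)
  pr <- vapply(kk, function(k) {
    x <- example_patient(); x$potassium <- k
    score_patient(x)$pr
  }, numeric(1))
  vertex <- 19.2919 / (2 * 2.329607)
  expect_equal(kk[which.min(pr)], vertex, tolerance = 1e-2)
  expect_true(all(diff(pr[kk < vertex - 0.01]) < 0))
  expect_true(all(diff(pr[kk > vertex + 0.01]) > 0))
})

test_that("coefficients and band tables round-trip through JSON files", {
  b <- suspekt_coefficients(b_age = 0.05)
  pb <- withr::local_tempfile(fileext = ".json")
  write_coefficients(b, pb)
  expect_equal(read_coefficients(pb), b)
  tab <- build_band_table(runif(40, 0.05, 0.95))
  pt <- withr::local_tempfile(fileext = ".json")
  write_band_table(tab, pt)
  expect_equal(read_band_table(pt), tab)
})

test_that("cohort scoring matches per-patient scoring row by row", {
  co <- generate_cohort(cohort_sim_config(n = 12, seed = 6))
  sc <- score_cohort(co)
  i <- 5
  one <- score_patient(list(glucose = co$glucose_mmol_l[i],
                            rel_total_volume = co$total_vol_cm3[i] / co$icv_cm3[i],
                            sbp = co$sbp_mmhg[i], ivh = co$ivh_present[i],
                            potassium = co$potassium_mmol_l[i],
                            age = co$age_years[i]))
  expect_equal(sc$pr[i], one$pr)
  expect_equal(sc$band_lower[i], one$band$lower_label)
  co$glucose_mmol_l[2] <- NA
  expect_message(sc2 <- score_cohort(co), "1 of 12")
  expect_true(is.na(sc2$pr[2]))
})
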