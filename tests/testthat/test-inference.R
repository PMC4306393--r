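test_that("model specs enforce term structure", {
  expect_error(model_spec("death30", list(list("k", 2))), "requires its linear term")
  expect_error(model_spec("death30", list("k", "k")), "duplicate")
  expect_error(model_spec("death30", list(list("k", 3))), "powers")
  sp <- model_spec("death30", list("a", list("k", 1), list("k", 2)))
  expect_length(sp$terms, 3)
})

test_that("a 2x2 logistic fit equals the closed-form log odds ratio", {
  # intraventricular blood vs death: 36/59 nonsurvivors, 16/66 survivors
  d <- data_2x2(n11 = 36, n10 = 23, n01 = 16, n00 = 50)
  fit <- fit_logistic(d, model_spec("death30", list("x")))
  lor <- log((36 / 23) / (16 / 50))
  se <- sqrt(1 / 36 + 1 / 23 + 1 / 16 + 1 / 50)
  expect_equal(unname(coef(fit)["x"]), lor, tolerance = 1e-6)
  expect_equal(fit$coefficients$se[fit$coefficients$term == "x"], se,
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_used, 125)
})

test_that("adding a term never decreases the log-likelihood", {
  co <- generate_cohort(cohort_sim_config(n = 300, seed = 14))
  f1 <- fit_logistic(co, model_spec("death30", list("glucose_mmol_l")))
  f2 <- fit_logistic(co, model_spec("death30", list("glucose_mmol_l", "age_years")))
  f3 <- fit_logistic(co, model_spec("death30", list(
    "glucose_mmol_l", "age_years", list("age_years", 2))))
  expect_gte(f2$log_likelihood, f1$log_likelihood - 1e-10)
  expect_gte(f3$log_likelihood, f2$log_likelihood - 1e-10)
})

test_that("an independent covariate fits near zero at large n", {
  set.seed(31)
  n <- 4000
  d <- data.frame(x = rnorm(n), death30 = rbinom(n, 1, 0.4))
  fit <- fit_logistic(d, model_spec("death30", list("x")))
  est <- coef(fit)["x"]
  se <- fit$coefficients$se[fit$coefficients$term == "x"]
  expect_lt(abs(est), 3 * se)
})

test_that("perfect separation is reported, not silently estimated", {
  d <- data.frame(x = c(rep(0, 12), rep(1, 12)),
                  death30 = c(rep(0, 12), rep(1, 12)))
  fit <- fit_logistic(d, model_spec("death30", list("x")))
  expect_false(fit$converged)
  expect_true(fit$separated)
})

test_that("degenerate inputs raise domain errors", {
  co <- generate_cohort(cohort_sim_config(n = 50, seed = 15))
  co$flat <- 1
  expect_error(fit_logistic(co, model_spec("death30", list("flat"))), "no variation")
  allsame <- co; allsame$death30 <- 1
  expect_error(fit_logistic(allsame, model_spec("death30", list("age_years"))),
               "single class")
  expect_error(fit_logistic(co[1:4, ], model_spec("death30", list("age_years"))),
               "too few")
  expect_error(univariable_screen(co, "flat"), "no variation")
})

test_that("univariable screening reports one joint LRT p per variable", {
  co <- generate_cohort(cohort_sim_config(n = 400, seed = 16))
  sc <- univariable_screen(co, c("glucose_mmol_l", "potassium_mmol_l"),
                           quadratic = c(glucose_mmol_l = FALSE,
                                         potassium_mmol_l = TRUE))
  expect_equal(nrow(sc$table), 2)
  # independent oracle: LRT via stats::anova on plain glm fits
  g1 <- glm(death30 ~ glucose_mmol_l, binomial, co)
  p1 <- anova(glm(death30 ~ 1, binomial, co), g1, test = "LRT")$`Pr(>Chi)`[2]
  expect_equal(sc$table$p_joint[1], p1, tolerance = 1e-8)
  g2 <- glm(death30 ~ potassium_mmol_l + I(potassium_mmol_l^2), binomial, co)
  p2 <- anova(glm(death30 ~ 1, binomial, co), g2, test = "LRT")$`Pr(>Chi)`[2]
  expect_equal(sc$table$p_joint[2], p2, tolerance = 1e-8)
  # the U-shaped potassium effect needs its quadratic term to show
  expect_lt(sc$table$p_joint[2], 0.05)
})

test_that("curvature check distinguishes linear from quadratic risk", {
  lin_dec <- quad_dec <- character(0)
  for (r in 1:25) {
    set.seed(100 + r)
    n <- 600
    x <- rnorm(n, 4, 1)
    lin <- data.frame(x = x, death30 = rbinom(n, 1, plogis(-2 + 0.5 * x)))
    qua <- data.frame(x = x, death30 = rbinom(n, 1, plogis(-2 + 0.9 * (x - 4)^2)))
    lin_dec[r] <- curvature_check(lin, "x")
    quad_dec[r] <- curvature_check(qua, "x")
  }
  expect_gte(mean(lin_dec == "linear"), 0.9)
  expect_gte(mean(quad_dec == "quadratic"), 0.9)
})

test_that("selection keeps remarkable variables and prunes collinear pairs", {
  tab <- data.frame(variable = c("a", "b", "c"), quadratic = FALSE,
                    n_used = 100, p_joint = c(0.02, 0.5, 0.03), converged = TRUE)
  corr <- diag(3); dimnames(corr) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_message(sp <- select_variables(tab, corr), "add-back step skipped")
  expect_setequal(vapply(sp$terms, `[[`, "", "field"), c("a", "c"))

  corr["a", "c"] <- corr["c", "a"] <- 0.9
  cfg <- selection_config(priorities = c(a = 1, c = 2))
  expect_message(sp2 <- select_variables(tab, corr, cfg))
  expect_setequal(vapply(sp2$terms, `[[`, "", "field"), "a")
  expect_error(suppressMessages(select_variables(tab, corr)), "priority")
})

test_that("a masked covariate returns through the add-back step", {
  set.seed(78)
  n <- 900
  u <- rnorm(n); v <- rnorm(n)
  d <- data.frame(x1 = u, x2 = (u + 2 * v) / sqrt(5),
                  death30 = rbinom(n, 1, plogis(2.2 * v)))
  sc <- univariable_screen(d, c("x1", "x2"))
  expect_gt(sc$table$p_joint[sc$table$variable == "x1"], 0.10)  # masked marginally
  expect_lt(sc$table$p_joint[sc$table$variable == "x2"], 0.10)
  corr <- cor(d[, c("x1", "x2")])
  sp <- select_variables(sc, corr, data = d)
  expect_setequal(vapply(sp$terms, `[[`, "", "field"), c("x2", "x1"))
})

test_that("Hosmer-Lemeshow is zero on a perfectly calibrated fixture", {
  p <- rep(c(0.1, 0.3, 0.5, 0.7), each = 10)
  y <- unlist(lapply(c(1, 3, 5, 7), function(k) c(rep(1, k), rep(0, 10 - k))))
  hl <- suppressMessages(hosmer_lemeshow(list(fitted = p, outcome = y), groups = 4))
  expect_equal(unname(hl$statistic), 0)
  expect_equal(hl$p.value, 1)
})

test_that("Hosmer-Lemeshow matches brute-force arithmetic and ignores order", {
  set.seed(19)
  p <- runif(90, 0.05, 0.95)
  y <- rbinom(90, 1, p)
  hl <- hosmer_lemeshow(list(fitted = p, outcome = y), groups = 3)
  # brute force: sort into 3 equal groups, evaluate the formula directly
  o <- order(p)
  gidx <- rep(1:3, each = 30)
  stat <- 0
  for (g in 1:3) {
    pg <- p[o][gidx == g]; yg <- y[o][gidx == g]
    E <- sum(pg); O <- sum(yg); ng <- length(pg)
    stat <- stat + (O - E)^2 / (E * (1 - E / ng))
  }
  expect_equal(unname(hl$statistic), stat, tolerance = 1e-9)
  expect_equal(unname(hl$parameter), 1)
  perm <- sample(90)
  hl2 <- hosmer_lemeshow(list(fitted = p[perm], outcome = y[perm]), groups = 3)
  expect_equal(hl2$statistic, hl$statistic, tolerance = 1e-12)
})

test_that("a well-specified model passes calibration at roughly the nominal rate", {
  rej <- logical(120)
  for (r in seq_along(rej)) {
    set.seed(500 + r)
    n <- 400
    x <- rnorm(n)
    d <- data.frame(x = x, death30 = rbinom(n, 1, plogis(-0.5 + x)))
    fit <- fit_logistic(d, model_spec("death30", list("x")))
    rej[r] <- suppressMessages(hosmer_lemeshow(fit))$p.value < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.06)
})

test_that("refitting a simulated cohort recovers the generating coefficients", {
  rp <- recover_parameters(n = 2000, seed = 8)
  expect_true(attr(rp, "converged"))
  expect_true(all(rp$within_3se))
  # the null coefficient is recovered as null
  cfg <- cohort_sim_config(coefficients = suspekt_coefficients(b_relvol = 0))
  rp0 <- recover_parameters(cfg, n = 2000, seed = 9)
  expect_lt(abs(rp0$estimate[rp0$term == "relvol"]),
            3 * rp0$se[rp0$term == "relvol"])
})
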