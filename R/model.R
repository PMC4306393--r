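#' The published SUSPEKT model
#'
#' Bundles a coefficient set and a percentile band table into a scoring
#' model. With no arguments this is the published learning-set model; pass
#' alternatives (e.g. loaded with [read_coefficients()]) to build a variant.
#'
#' @param coefficients a [suspekt_coefficients()] object.
#' @param bands a [suspekt_band_table()] object.
#' @return An object of class `suspekt_model`.
#' @seealso [fit_suspekt()] to estimate a model from cohort data.
#' @export
#' @examples
#' m <- suspekt_model()
#' predict(m, generate_cohort(cohort_sim_config(n = 5)))
suspekt_model <- function(coefficients = suspekt_coefficients(),
                          bands = suspekt_band_table()) {
  stopifnot(inherits(coefficients, "suspekt_coefficients"),
            inherits(bands, "band_table"))
  structure(list(coefficients = coefficients, bands = bands, fit = NULL,
                 call = match.call()),
            class = "suspekt_model")
}

#' Fit the six-factor model to a cohort
#'
#' Estimates the six-factor logistic model (glucose, relative total
#' haematoma volume, systolic blood pressure, intraventricular extension,
#' potassium with a raw-scale quadratic term, age) on a cohort data frame by
#' maximum likelihood, and derives the percentile band table from the
#' fitted probabilities, mirroring how the published score was built on its
#' learning set.
#'
#' @param data cohort data frame in the [cohort_schema()] layout.
#' @param outcome outcome column, default `"death30"`.
#' @param band_method percentile method for [build_band_table()].
#' @return A `suspekt_model` whose `fit` element is the underlying
#'   [fit_logistic()] result.
#' @export
fit_suspekt <- function(data, outcome = "death30",
                        band_method = c("nearest_rank", "linear")) {
  band_method <- match.arg(band_method)
  data$rel_total <- data$total_vol_cm3 / data$icv_cm3
  spec <- model_spec(outcome, list(
    "glucose_mmol_l", "rel_total", "sbp_mmhg", "ivh_present",
    "potassium_mmol_l", list("potassium_mmol_l", 2), "age_years"))
  fit <- fit_logistic(data, spec)
  cf <- coef(fit)
  b <- suspekt_coefficients(
    b_glucose = cf[["glucose_mmol_l"]],
    b_relvol = cf[["rel_total"]],
    b_sbp = cf[["sbp_mmhg"]],
    b_ivh = cf[["ivh_present"]],
    b_potassium = cf[["potassium_mmol_l"]],
    b_potassium_sq = cf[["I(potassium_mmol_l^2)"]],
    b_age = cf[["age_years"]],
    constant = cf[["(Intercept)"]])
  bands <- build_band_table(pmin(pmax(fit$fitted, 1e-12), 1 - 1e-12),
                            method = band_method)
  structure(list(coefficients = b, bands = bands, fit = fit,
                 call = match.call()),
            class = "suspekt_model")
}

#' @export
print.suspekt_model <- function(x, ...) {
  cat(if (is.null(x$fit)) "SUSPEKT prognostic model (published coefficients)\n"
      else sprintf("SUSPEKT prognostic model (refitted, n = %d)\n", x$fit$n_used))
  print(x$coefficients)
  k_min <- -unclass(x$coefficients)[["potassium"]] /
    (2 * unclass(x$coefficients)[["potassium_sq"]])
  cat(sprintf("potassium of minimum predicted risk: %.2f mmol/L\n", k_min))
  invisible(x)
}

#' @export
coef.suspekt_model <- function(object, ...) unclass(object$coefficients)

#' @export
summary.suspekt_model <- function(object, ...) {
  if (is.null(object$fit)) return(print(object))
  summary(object$fit)
}

#' Score a cohort with a model
#'
#' @param object a `suspekt_model`.
#' @param newdata cohort data frame in the [cohort_schema()] layout.
#' @param ... unused.
#' @return The [score_cohort()] data.frame (`patient_id`, `sbx`, `pr`, band
#'   labels).
#' @export
predict.suspekt_model <- function(object, newdata, ...) {
  score_cohort(newdata, b = object$coefficients, table = object$bands)
}

#' @export
residuals.suspekt_model <- function(object, ...) {
  if (is.null(object$fit)) .stopf("the published model carries no training data")
  residuals(object$fit, ...)
}

#' Simulate cohorts from a model
#'
#' Draws synthetic admission cohorts whose 30-day outcome is generated
#' through the model's own score probability (see [generate_cohort()]).
#'
#' @param object a `suspekt_model`.
#' @param nsim number of cohorts.
#' @param seed RNG seed for the first cohort; cohort `i` uses `seed + i - 1`.
#' @param n patients per cohort.
#' @param ... passed to [cohort_sim_config()].
#' @return A list of `nsim` cohort data.frames.
#' @export
simulate.suspekt_model <- function(object, nsim = 1, seed = 1, n = 125, ...) {
  lapply(seq_len(nsim), function(i) {
    generate_cohort(cohort_sim_config(n = n, seed = seed + i - 1,
                                      coefficients = object$coefficients, ...))
  })
}

#' Plot a model
#'
#' For any model, draws the U-shaped predicted risk across serum potassium
#' with the remaining factors held at the worked-example means. For a
#' refitted model a calibration panel (observed vs expected deaths per risk
#' decile) is added.
#'
#' @param x a `suspekt_model`.
#' @param k_range potassium range to display, mmol/L.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.suspekt_model <- function(x, k_range = c(2.5, 6.5), ...) {
  has_fit <- !is.null(x$fit)
  if (has_fit) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  ex <- suspekt_worked_example()$x
  kk <- seq(k_range[1], k_range[2], length.out = 200)
  pr <- vapply(kk, function(k) {
    ex$potassium <- k
    score_patient(ex, b = x$coefficients, table = x$bands)$pr
  }, numeric(1))
  graphics::plot(kk, pr, type = "l", xlab = "serum potassium (mmol/L)",
                 ylab = "predicted probability of 30-day death",
                 main = "Potassium risk profile (other factors at cohort means)")
  graphics::abline(v = kk[which.min(pr)], lty = 3)
  if (has_fit) {
    hl <- hosmer_lemeshow(x$fit)
    g <- hl$groups
    graphics::plot(g$expected, g$observed, xlab = "expected deaths",
                   ylab = "observed deaths",
                   main = sprintf("Calibration (HL p = %.3f)", hl$p.value))
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
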