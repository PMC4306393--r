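#' SUSPEKT score coefficients
#'
#' The coefficient vector and constant of the published six-factor SUSPEKT
#' model: serum glucose (SU), relative total haematoma volume (S), admission
#' systolic blood pressure (P), intraventricular extension (E), serum
#' potassium with a quadratic term (K), and age (T). The potassium effect is
#' U-shaped: the linear and squared coefficients place minimum risk near
#' 4.14 mmol/L, so both hypo- and hyperkalaemia raise the predicted odds of
#' death.
#'
#' Defaults are the published learning-set estimates. Supply alternatives
#' (e.g. from [fit_suspekt()] or [read_coefficients()]) to rescore under a
#' refitted model.
#'
#' @param b_glucose coefficient per mmol/L serum glucose.
#' @param b_relvol coefficient per unit relative total haematoma volume
#'   (haematoma volume / intracranial volume, dimensionless).
#' @param b_sbp coefficient per mm Hg systolic blood pressure.
#' @param b_ivh coefficient for presence of intraventricular blood (0/1).
#' @param b_potassium coefficient per mmol/L serum potassium (linear term).
#' @param b_potassium_sq coefficient per (mmol/L)^2 (quadratic term).
#' @param b_age coefficient per year of age.
#' @param constant model intercept.
#' @return An object of class `suspekt_coefficients`: a named numeric vector
#'   of length 8 in factor order (glucose, relvol, sbp, ivh, potassium,
#'   potassium_sq, age, constant).
#' @seealso [score_patient()], [partial_products()], [fit_suspekt()]
#' @export
#' @examples
#' suspekt_coefficients()
suspekt_coefficients <- function(b_glucose = 0.105504,
                                 b_relvol = 68.94767,
                                 b_sbp = 0.003043,
                                 b_ivh = 0.441198,
                                 b_potassium = -19.2919,
                                 b_potassium_sq = 2.329607,
                                 b_age = 0.040057,
                                 constant = 33.54228) {
  b <- c(glucose = b_glucose, relvol = b_relvol, sbp = b_sbp, ivh = b_ivh,
         potassium = b_potassium, potassium_sq = b_potassium_sq,
         age = b_age, constant = constant)
  .check_number(b, "coefficients")
  structure(b, class = "suspekt_coefficients")
}

#' @export
print.suspekt_coefficients <- function(x, digits = 6, ...) {
  cat("SUSPEKT score coefficients (log-odds scale)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

.score_factors <- c("glucose", "rel_total_volume", "sbp", "ivh", "potassium", "age")

.check_score_input <- function(x) {
  for (f in .score_factors) {
    v <- x[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v) || !is.finite(as.numeric(v)))
      .stopf("scoring error: factor '%s' is missing or non-finite", f)
  }
  if (x[["potassium"]] <= 0)
    .stopf("scoring error: factor 'potassium' must be strictly positive")
  lapply(x[.score_factors], as.numeric)
}

#' Per-factor coefficient-times-value products
#'
#' Multiplies each patient value by its coefficient, yielding the eight
#' partial products whose sum is the linear predictor: the six clinical
#' factors, the internally computed potassium-squared term, and the constant.
#' The squared potassium term is always derived from `potassium` itself, so
#' the two rows can never disagree.
#'
#' @param x a list (or one-row data.frame) with elements `glucose` (mmol/L),
#'   `rel_total_volume` (dimensionless), `sbp` (mm Hg), `ivh` (0/1, or a
#'   fraction for cohort-mean illustration), `potassium` (mmol/L), `age`
#'   (years).
#' @param b a [suspekt_coefficients()] object.
#' @return Named numeric vector of length 8 (glucose, relvol, sbp, ivh,
#'   potassium, potassium_sq, age, constant).
#' @export
#' @examples
#' partial_products(list(glucose = 8.097, rel_total_volume = 0.027,
#'                       sbp = 174.728, ivh = 0.416, potassium = 4.054,
#'                       age = 67.168))
partial_products <- function(x, b = suspekt_coefficients()) {
  stopifnot(inherits(b, "suspekt_coefficients"))
  v <- .check_score_input(x)
  xx <- c(glucose = v$glucose, relvol = v$rel_total_volume, sbp = v$sbp,
          ivh = v$ivh, potassium = v$potassium,
          potassium_sq = v$potassium^2, age = v$age, constant = 1)
  unclass(b) * xx
}

#' Linear predictor from partial products
#'
#' Sums the eight coefficient-times-value products into the linear predictor
#' (log-odds of death within 30 days).
#'
#' @param bx numeric vector of length 8, as returned by [partial_products()].
#' @return The scalar linear predictor.
#' @export
linear_predictor <- function(bx) {
  if (length(bx) != 8) .stopf("expected 8 partial products, got %d", length(bx))
  .check_number(bx, "bx")
  sum(bx)
}

#' Logistic transform of the linear predictor
#'
#' Converts a linear predictor to a probability of death within 30 days via
#' the logistic function \eqn{e^{s}/(1+e^{s})}, using a symmetric form that is
#' numerically stable for |s| up to at least 700.
#'
#' @param sbx finite numeric linear predictor (vectorised).
#' @return Probability in (0, 1) (0 or 1 only when the linear predictor
#'   under/overflows double precision, beyond roughly |s| = 745).
#' @export
#' @examples
#' score_probability(0)        # 0.5
#' score_probability(-0.2749)  # the published worked example, ~0.4317
score_probability <- function(sbx) {
  .check_number(sbx, "sbx")
  .expit(sbx)
}

#' Percentile band table
#'
#' The 11 probability anchors (minimum, 10th--90th percentiles, maximum) of
#' the model-predicted death probabilities over the learning cohort. A new
#' patient's probability is reported relative to these anchors, placing the
#' patient within the learning-set risk distribution.
#'
#' @param anchors non-decreasing numeric vector of 11 probabilities in
#'   (0, 1). Defaults to the published learning-set table.
#' @return An object of class `band_table`.
#' @seealso [assign_band()], [build_band_table()]
#' @export
suspekt_band_table <- function(anchors = c(0.036732, 0.095083, 0.133933,
                                           0.190302, 0.263309, 0.376832,
                                           0.516875, 0.769061, 0.918411,
                                           0.975373, 0.999965)) {
  if (length(anchors) != 11) .stopf("a band table needs exactly 11 anchors, got %d", length(anchors))
  .check_number(anchors, "anchors")
  if (any(anchors <= 0 | anchors >= 1)) .stopf("band anchors must lie strictly in (0, 1)")
  if (is.unsorted(anchors)) .stopf("band table anchors must be non-decreasing")
  names(anchors) <- .band_labels
  structure(anchors, class = "band_table")
}

.band_labels <- c("minimum", paste0(seq(10, 90, 10), "th"), "maximum")

#' @export
print.band_table <- function(x, ...) {
  cat("Risk percentile band table (learning-set predicted probabilities)\n")
  print(data.frame(anchor = names(unclass(x)), probability = as.numeric(x)),
        row.names = FALSE)
  invisible(x)
}

#' Derive a band table from predicted probabilities
#'
#' Computes the 11 anchors (minimum, 10th--90th percentiles, maximum) from a
#' sample of model-predicted probabilities, as done on the learning cohort.
#'
#' @param probabilities numeric vector (length >= 10) of probabilities in
#'   (0, 1).
#' @param method percentile method: `"nearest_rank"` (default; the
#'   ceiling(q*n)-th order statistic) or `"linear"` (interpolated, type-7
#'   quantiles).
#' @return A [suspekt_band_table()] object.
#' @export
build_band_table <- function(probabilities,
                             method = c("nearest_rank", "linear")) {
  method <- match.arg(method)
  p <- probabilities
  if (length(p) < 10)
    .stopf("band table needs at least 10 probabilities, got %d", length(p))
  .check_number(p, "probabilities")
  if (any(p <= 0 | p >= 1)) .stopf("probabilities must lie strictly in (0, 1)")
  q <- seq(0.1, 0.9, by = 0.1)
  mid <- if (method == "nearest_rank") {
    sort(p)[ceiling(q * length(p))]
  } else {
    unname(stats::quantile(p, probs = q, type = 7))
  }
  suspekt_band_table(c(min(p), mid, max(p)))
}

#' Place a probability within the band table
#'
#' Brackets a probability between adjacent anchors using half-open
#' lower-inclusive intervals `[anchor_k, anchor_{k+1})`. Probabilities below
#' the minimum are flagged `below_min`; probabilities at or above the maximum
#' fall in the top band, with `above_max` set when strictly greater than the
#' maximum.
#'
#' @param pr probability in (0, 1).
#' @param table a [suspekt_band_table()] object.
#' @return An object of class `band_assignment` with elements `lower_label`,
#'   `upper_label`, `lower`, `upper` (anchor values), `lower_percentile`
#'   (0 for minimum, 10--90 for deciles, NA below the minimum), `below_min`
#'   and `above_max` flags.
#' @export
#' @examples
#' assign_band(0.432)  # between the 50th and 60th learning-set percentiles
assign_band <- function(pr, table = suspekt_band_table()) {
  if (!inherits(table, "band_table")) table <- suspekt_band_table(table)
  .check_number(pr, "pr")
  if (length(pr) != 1) .stopf("'pr' must be a single probability")
  a <- as.numeric(table)
  labs <- names(unclass(table))
  if (pr < a[1]) {
    out <- list(lower_label = "below-min", upper_label = labs[1],
                lower = NA_real_, upper = a[1],
                lower_percentile = NA_real_,
                below_min = TRUE, above_max = FALSE)
  } else if (pr >= a[11]) {
    out <- list(lower_label = labs[10], upper_label = labs[11],
                lower = a[10], upper = a[11],
                lower_percentile = 90,
                below_min = FALSE, above_max = pr > a[11])
  } else {
    k <- findInterval(pr, a)  # half-open lower-inclusive by default
    out <- list(lower_label = labs[k], upper_label = labs[k + 1],
                lower = a[k], upper = a[k + 1],
                lower_percentile = if (k == 1) 0 else (k - 1) * 10,
                below_min = FALSE, above_max = FALSE)
  }
  structure(out, class = "band_assignment")
}

#' @export
print.band_assignment <- function(x, ...) {
  if (x$below_min) {
    cat(sprintf("below the learning-set minimum (%.6f)\n", x$upper))
  } else if (x$above_max) {
    cat(sprintf("above the learning-set maximum (%.6f)\n", x$upper))
  } else {
    cat(sprintf("between the %s and %s learning-set percentiles [%.6f, %.6f)\n",
                x$lower_label, x$upper_label, x$lower, x$upper))
  }
  invisible(x)
}

#' Score one patient
#'
#' Full SUSPEKT scoring: per-factor products, linear predictor, probability
#' of death within 30 days, and percentile-band placement against the
#' learning-set band table.
#'
#' @inheritParams partial_products
#' @param table a [suspekt_band_table()] object.
#' @return An object of class `score_result` with elements `bx` (8 partial
#'   products), `sbx` (linear predictor), `pr` (probability) and `band`
#'   (a `band_assignment`).
#' @export
#' @examples
#' score_patient(list(glucose = 8.097, rel_total_volume = 0.027,
#'                    sbp = 174.728, ivh = 0.416, potassium = 4.054,
#'                    age = 67.168))
score_patient <- function(x, b = suspekt_coefficients(),
                          table = suspekt_band_table()) {
  bx <- partial_products(x, b)
  sbx <- linear_predictor(bx)
  pr <- score_probability(sbx)
  structure(list(bx = bx, sbx = sbx, pr = pr, band = assign_band(pr, table)),
            class = "score_result")
}

#' @export
print.score_result <- function(x, digits = 6, ...) {
  cat("SUSPEKT score\n")
  print(round(x$bx, digits))
  cat(sprintf("linear predictor (sbx): %.*f\n", digits, x$sbx))
  cat(sprintf("probability of 30-day death (pr): %.*f\n", digits, x$pr))
  cat("risk band: ")
  print(x$band)
  invisible(x)
}

#' Score every patient in a cohort
#'
#' Applies [score_patient()] row-wise to a cohort data frame in the package
#' CSV schema (see [read_cohort()]). The relative total haematoma volume is
#' taken as `total_vol_cm3 / icv_cm3`. Rows missing any required factor are
#' returned with `NA` score fields and counted in a message (complete-case
#' policy).
#'
#' @param records cohort data frame.
#' @inheritParams score_patient
#' @return A data.frame with columns `patient_id`, `sbx`, `pr`,
#'   `band_lower`, `band_upper`.
#' @export
score_cohort <- function(records, b = suspekt_coefficients(),
                         table = suspekt_band_table()) {
  need <- c("glucose_mmol_l", "total_vol_cm3", "icv_cm3", "sbp_mmhg",
            "ivh_present", "potassium_mmol_l", "age_years")
  miss <- setdiff(need, names(records))
  if (length(miss)) .stopf("cohort is missing column(s): %s", paste(miss, collapse = ", "))
  n <- nrow(records)
  out <- data.frame(patient_id = as.character(records$patient_id),
                    sbx = NA_real_, pr = NA_real_,
                    band_lower = NA_character_, band_upper = NA_character_,
                    stringsAsFactors = FALSE)
  ok <- stats::complete.cases(records[need])
  for (i in which(ok)) {
    r <- records[i, ]
    s <- score_patient(list(glucose = r$glucose_mmol_l,
                            rel_total_volume = r$total_vol_cm3 / r$icv_cm3,
                            sbp = r$sbp_mmhg, ivh = r$ivh_present,
                            potassium = r$potassium_mmol_l,
                            age = r$age_years), b = b, table = table)
    out$sbx[i] <- s$sbx
    out$pr[i] <- s$pr
    out$band_lower[i] <- s$band$lower_label
    out$band_upper[i] <- s$band$upper_label
  }
  if (any(!ok))
    message(sprintf("score_cohort: %d of %d records dropped (incomplete factors)",
                    sum(!ok), n))
  out
}

#' The published worked scoring example
#'
#' The cohort-mean patient used to illustrate the score: the factor values
#' `x` (means of the learning cohort, hence the fractional intraventricular
#' indicator), and the printed per-factor products `bx` whose sum is the
#' published linear predictor. Because the printed `x` are rounded means,
#' re-multiplying them by the coefficients reproduces the printed products
#' only to ~0.02; the printed `bx` column is the authoritative arithmetic.
#'
#' @return A list with elements `x` (score input list) and `bx` (named
#'   numeric vector of the eight printed products).
#' @export
suspekt_worked_example <- function() {
  list(
    x = list(glucose = 8.097, rel_total_volume = 0.027, sbp = 174.728,
             ivh = 0.416, potassium = 4.054, age = 67.168),
    bx = c(glucose = 0.854244, relvol = 1.845598, sbp = 0.53161,
           ivh = 0.183538, potassium = -78.2126, potassium_sq = 38.28992,
           age = 2.690528, constant = 33.54228)
  )
}
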