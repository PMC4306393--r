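# Refitting machinery: logistic regression with curvature handling,
# univariable screening, variable selection, and calibration checking.

#' Model specification
#'
#' A logistic-model specification: the binary outcome column, an ordered
#' list of `(field, power)` terms (power 2 = raw-scale squared term, which
#' requires its linear term), and whether to include an intercept.
#'
#' @param outcome outcome column name (coded 0/1).
#' @param terms list of terms; each either a field name (power 1) or a
#'   `list(field, power)` / `c(field, power)` pair with power 1 or 2.
#' @param include_constant include an intercept (default `TRUE`).
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("death30", list("glucose_mmol_l", list("potassium_mmol_l", 2)))
model_spec <- function(outcome, terms, include_constant = TRUE) {
  norm <- lapply(terms, function(t) {
    if (is.character(t) && length(t) == 1) return(list(field = t, power = 1L))
    f <- as.character(t[[1]]); p <- as.integer(t[[2]])
    if (!p %in% c(1L, 2L)) .stopf("term powers must be 1 or 2, got %d", p)
    list(field = f, power = p)
  })
  key <- vapply(norm, function(t) paste0(t$field, "^", t$power), character(1))
  if (anyDuplicated(key)) .stopf("duplicate model term: %s", key[duplicated(key)][1])
  for (t in norm) {
    if (t$power == 2L && !paste0(t$field, "^1") %in% key)
      .stopf("squared term for '%s' requires its linear term", t$field)
  }
  structure(list(outcome = outcome, terms = norm,
                 include_constant = isTRUE(include_constant)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  lab <- vapply(x$terms, function(t)
    if (t$power == 1) t$field else sprintf("I(%s^2)", t$field), character(1))
  cat(sprintf("%s ~ %s%s\n", x$outcome, paste(lab, collapse = " + "),
              if (x$include_constant) "" else " - 1"))
  invisible(x)
}

.spec_fields <- function(spec) unique(vapply(spec$terms, `[[`, character(1), "field"))

.spec_formula <- function(spec) {
  lab <- vapply(spec$terms, function(t)
    if (t$power == 1) t$field else sprintf("I(%s^2)", t$field), character(1))
  rhs <- if (length(lab)) paste(lab, collapse = " + ") else "1"
  if (!spec$include_constant) rhs <- paste(rhs, "- 1")
  stats::as.formula(paste(spec$outcome, "~", rhs))
}

#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic regression for a [model_spec()], fitted by
#' iteratively reweighted least squares (via [stats::glm()], convergence
#' tolerance 1e-8, at most 100 iterations) on the complete cases. Wald
#' standard errors and p-values are reported per term. Complete or
#' quasi-complete separation — diagnosed from boundary fitted probabilities
#' together with a diverging standardised coefficient norm — is flagged as
#' non-convergence rather than reported as silent estimates.
#'
#' @param data cohort data frame.
#' @param spec a [model_spec()].
#' @return An object of class `suspekt_fit` with elements `coefficients`
#'   (data.frame: estimate, se, z, p), `log_likelihood`, `converged`,
#'   `separated`, `n_used`, `spec`, `fitted`, `outcome` and the underlying
#'   `glm` object.
#' @export
fit_logistic <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- c(spec$outcome, .spec_fields(spec))
  miss <- setdiff(cols, names(data))
  if (length(miss)) .stopf("data is missing column(s): %s", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (nrow(d) < length(spec$terms) + 5)
    .stopf("too few complete cases (%d) for %d term(s)", nrow(d), length(spec$terms))
  y <- d[[spec$outcome]]
  if (!all(y %in% c(0, 1))) .stopf("outcome '%s' must be coded 0/1", spec$outcome)
  if (length(unique(y)) < 2) .stopf("outcome '%s' has a single class", spec$outcome)
  for (f in .spec_fields(spec))
    if (stats::sd(d[[f]]) == 0) .stopf("covariate '%s' has no variation", f)
  fit <- withCallingHandlers(
    stats::glm(.spec_formula(spec), family = stats::binomial(), data = d,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # separation: fitted probabilities driven to the boundary together with a
  # diverging standardised coefficient norm (|beta_j| * sd(x_j) stays
  # moderate for any well-identified fit)
  boundary <- any(fit$fitted.values > 1 - 1e-10 | fit$fitted.values < 1e-10)
  mm <- stats::model.matrix(fit)
  sds <- apply(mm, 2, stats::sd)
  keep <- colnames(mm) != "(Intercept)"  # the intercept scale is arbitrary
  separated <- boundary && any(keep) &&
    max(abs(est[keep]) * sds[keep], na.rm = TRUE) > 15 &&
    max(se[keep] * sds[keep], na.rm = TRUE) > 10
  converged <- isTRUE(fit$converged) && !separated
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(est / se),
                      p = unname(2 * stats::pnorm(-abs(est / se))),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 converged = converged, separated = separated,
                 n_used = nrow(d), spec = spec,
                 fitted = unname(stats::fitted(fit)), outcome = y, glm = fit),
            class = "suspekt_fit")
}

#' @export
print.suspekt_fit <- function(x, digits = 4, ...) {
  print(x$spec)
  stats::printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "z", "p")]),
               digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("n = %d, log-likelihood = %.3f, converged: %s%s\n",
              x$n_used, x$log_likelihood, x$converged,
              if (x$separated) " (separation detected)" else ""))
  invisible(x)
}

#' @export
coef.suspekt_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.suspekt_fit <- function(object, ...) stats::logLik(object$glm)

#' @export
vcov.suspekt_fit <- function(object, ...) stats::vcov(object$glm)

#' @export
predict.suspekt_fit <- function(object, newdata = NULL,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted)
    return(unname(stats::predict(object$glm, type = "link")))
  }
  unname(stats::predict(object$glm, newdata = newdata, type = type))
}

#' @export
residuals.suspekt_fit <- function(object, type = "deviance", ...) {
  unname(stats::residuals(object$glm, type = type))
}

#' @export
summary.suspekt_fit <- function(object, ...) {
  out <- object$coefficients
  out$odds_ratio <- exp(out$estimate)
  structure(list(spec = object$spec, table = out, n_used = object$n_used,
                 log_likelihood = object$log_likelihood,
                 converged = object$converged),
            class = "summary.suspekt_fit")
}

#' @export
print.summary.suspekt_fit <- function(x, ...) {
  print(x$spec)
  print(x$table, row.names = FALSE, digits = 5)
  cat(sprintf("n = %d, log-likelihood = %.3f, converged: %s\n",
              x$n_used, x$log_likelihood, x$converged))
  invisible(x)
}

# likelihood-ratio p-value between nested fits
.lrt_p <- function(full, null, df) {
  stat <- 2 * (full$log_likelihood - null$log_likelihood)
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Univariable screening with optional quadratic terms
#'
#' Fits one single-covariate logistic model per variable (adding a raw-scale
#' squared term where flagged) and reports a joint likelihood-ratio p-value
#' for the variable's terms against the intercept-only model on the same
#' complete cases — so a quadratic-flagged variable gets one p-value, not
#' two.
#'
#' @param data cohort data frame.
#' @param variables character vector of covariate columns.
#' @param quadratic logical vector (recycled or named by variable): add a
#'   squared term for this variable. Default all `FALSE`.
#' @param outcome outcome column, default `"death30"`.
#' @return A list with `table` (data.frame: variable, quadratic, n_used,
#'   p_joint, converged) and `fits` (named list of [fit_logistic()] results).
#' @export
univariable_screen <- function(data, variables, quadratic = FALSE,
                               outcome = "death30") {
  if (is.null(names(quadratic))) {
    quadratic <- rep_len(quadratic, length(variables))
    names(quadratic) <- variables
  }
  fits <- list()
  tab <- data.frame(variable = variables, quadratic = FALSE, n_used = NA_integer_,
                    p_joint = NA_real_, converged = NA, stringsAsFactors = FALSE)
  for (i in seq_along(variables)) {
    v <- variables[i]
    quad <- isTRUE(quadratic[[v]])
    terms <- if (quad) list(v, list(v, 2)) else list(v)
    fit <- fit_logistic(data, model_spec(outcome, terms))
    cc <- data[stats::complete.cases(data[c(outcome, v)]), , drop = FALSE]
    null <- fit_logistic(cc, model_spec(outcome, list(), include_constant = TRUE))
    tab$quadratic[i] <- quad
    tab$n_used[i] <- fit$n_used
    tab$p_joint[i] <- .lrt_p(fit, null, df = 1 + quad)
    tab$converged[i] <- fit$converged
    fits[[v]] <- fit
  }
  list(table = tab, fits = fits)
}

#' Decide between a linear and a quadratic term
#'
#' Compares the single-covariate logistic model with and without a raw-scale
#' squared term by a 1-df likelihood-ratio test; the quadratic is kept iff it
#' substantially improves fit (p below `threshold`).
#'
#' @param data cohort data frame.
#' @param variable covariate column.
#' @param threshold LRT significance threshold, default 0.05.
#' @param outcome outcome column, default `"death30"`.
#' @return `"quadratic"` or `"linear"`, with attributes `p` and `lrt`.
#' @export
curvature_check <- function(data, variable, threshold = 0.05,
                            outcome = "death30") {
  cc <- data[stats::complete.cases(data[c(outcome, variable)]), , drop = FALSE]
  lin <- fit_logistic(cc, model_spec(outcome, list(variable)))
  quad <- fit_logistic(cc, model_spec(outcome, list(variable, list(variable, 2))))
  p <- .lrt_p(quad, lin, df = 1)
  structure(if (p < threshold) "quadratic" else "linear",
            p = p, lrt = 2 * (quad$log_likelihood - lin$log_likelihood))
}

#' Selection configuration
#'
#' @param p_threshold screening p-value below which an association counts as
#'   remarkable (default 0.10).
#' @param collinearity_threshold absolute correlation above which two
#'   selected variables are treated as collinear (default 0.7).
#' @param priorities named numeric vector; for a collinear pair the variable
#'   with the *smaller* value is retained (clinical practicability is a
#'   judgement call, so priorities are supplied, never inferred).
#' @param addback_threshold p-value below which a left-out variable added to
#'   the prefinal model is brought back in (default 0.05).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 0.10, collinearity_threshold = 0.7,
                             priorities = numeric(), addback_threshold = 0.05) {
  structure(list(p_threshold = p_threshold,
                 collinearity_threshold = collinearity_threshold,
                 priorities = priorities,
                 addback_threshold = addback_threshold),
            class = "selection_config")
}

#' Select variables for the multivariable model
#'
#' Implements the screening-then-pruning strategy: keep variables whose
#' univariable (joint) p-value is below the remarkable-association
#' threshold; among collinear pairs drop the lower-priority member; then
#' re-offer each variable left out at screening to the prefinal model one by
#' one, keeping it if its addition is significant.
#'
#' @param screen result of [univariable_screen()] (or its `table`).
#' @param correlations correlation matrix of the candidate variables
#'   (dimnames must cover the screened variables).
#' @param config a [selection_config()].
#' @param data cohort data frame; needed for the add-back step (skipped with
#'   a message when `NULL`).
#' @param outcome outcome column, default `"death30"`.
#' @return A [model_spec()] for the selected model (quadratic flags carried
#'   through from screening).
#' @export
select_variables <- function(screen, correlations, config = selection_config(),
                             data = NULL, outcome = "death30") {
  tab <- if (is.list(screen) && !is.data.frame(screen)) screen$table else screen
  stopifnot(inherits(config, "selection_config"))
  sel <- tab$variable[tab$p_joint < config$p_threshold]
  left_out <- setdiff(tab$variable, sel)
  # prune collinear pairs among the selected
  if (length(sel) > 1) {
    for (i in seq_along(sel)) for (j in seq_along(sel)) {
      if (i >= j) next
      a <- sel[i]; b <- sel[j]
      if (is.na(a) || is.na(b)) next
      r <- correlations[a, b]
      if (!is.na(r) && abs(r) > config$collinearity_threshold) {
        pa <- config$priorities[a]; pb <- config$priorities[b]
        if (is.na(pa) || is.na(pb) || length(pa) == 0 || length(pb) == 0)
          .stopf("collinear pair (%s, %s) but no priority given for both", a, b)
        drop <- if (pa <= pb) b else a
        sel[sel == drop] <- NA_character_
      }
    }
    sel <- sel[!is.na(sel)]
  }
  quad_of <- function(v) isTRUE(tab$quadratic[tab$variable == v])
  mk_terms <- function(vars) {
    out <- list()
    for (v in vars) {
      out <- c(out, list(v))
      if (quad_of(v)) out <- c(out, list(list(v, 2)))
    }
    out
  }
  # re-offer screening rejects against the prefinal model
  if (length(left_out)) {
    if (is.null(data)) {
      message("select_variables: no data supplied; add-back step skipped")
    } else {
      for (v in left_out) {
        # both fits on the complete cases of the augmented model
        cc <- data[stats::complete.cases(data[c(outcome, sel, v)]), , drop = FALSE]
        cand <- fit_logistic(cc, model_spec(outcome, mk_terms(c(sel, v))))
        df <- 1 + quad_of(v)
        pre_cc <- fit_logistic(cc, model_spec(outcome, mk_terms(sel)))
        if (.lrt_p(cand, pre_cc, df = df) < config$addback_threshold)
          sel <- c(sel, v)
      }
    }
  }
  model_spec(outcome, mk_terms(sel))
}

#' Hosmer-Lemeshow calibration test
#'
#' Deciles-of-risk goodness-of-fit check: patients are grouped by predicted
#' probability, and observed vs model-expected event counts are compared via
#' \eqn{\sum_g (O_g - E_g)^2 / (E_g (1 - E_g / n_g))}, referred to a
#' chi-squared distribution with `groups - 2` degrees of freedom. Groups
#' emptied by probability ties are merged with their neighbour (message).
#'
#' @param fit a [fit_logistic()] result, or a list with elements `fitted`
#'   (predicted probabilities) and `outcome` (0/1).
#' @param groups number of risk groups (default 10, minimum 3).
#' @return An object of classes `suspekt_hl` and `htest`, with a `groups`
#'   data.frame (n, expected, observed, mean_p) attached.
#' @export
hosmer_lemeshow <- function(fit, groups = 10) {
  p <- fit$fitted
  y <- fit$outcome
  if (is.null(p) || is.null(y) || length(p) != length(y))
    .stopf("fit must provide matching 'fitted' probabilities and a 0/1 'outcome'")
  if (groups < 3) .stopf("at least 3 risk groups are required")
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1)))
  if (length(br) - 1 < groups)
    message(sprintf("hosmer_lemeshow: ties reduced %d groups to %d", groups, length(br) - 1))
  if (length(br) - 1 < 3) .stopf("fewer than 3 distinct risk groups after tying")
  g <- cut(p, breaks = br, include.lowest = TRUE)
  tab <- data.frame(
    n = as.vector(table(g)),
    expected = as.vector(tapply(p, g, sum)),
    observed = as.vector(tapply(y, g, sum)),
    mean_p = as.vector(tapply(p, g, mean)))
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  df <- nrow(tab) - 2
  out <- list(statistic = c("X-squared" = stat), parameter = c(df = df),
              p.value = stats::pchisq(stat, df, lower.tail = FALSE),
              method = "Hosmer-Lemeshow goodness-of-fit test (deciles of risk)",
              data.name = deparse(substitute(fit)), groups = tab)
  class(out) <- c("suspekt_hl", "htest")
  out
}

#' Parameter-recovery check for the generator/fitter pair
#'
#' Simulates a cohort whose outcome is generated through the SUSPEKT
#' probability with known coefficients, refits the six-factor model, and
#' reports per-coefficient bias and whether each generating value lies
#' within ±3 standard errors of its estimate.
#'
#' @param config a [cohort_sim_config()]; its `coefficients` are the truth.
#' @param n cohort size (overrides `config$n`).
#' @param seed RNG seed (overrides `config$seed`).
#' @return A data.frame (term, truth, estimate, se, bias, within_3se) with
#'   attribute `converged`.
#' @export
recover_parameters <- function(config = cohort_sim_config(), n = 5000,
                               seed = 1) {
  config$n <- n
  config$seed <- seed
  cohort <- generate_cohort(config)
  cohort$rel_total <- cohort$total_vol_cm3 / cohort$icv_cm3
  spec <- model_spec("death30", list(
    "glucose_mmol_l", "rel_total", "sbp_mmhg", "ivh_present",
    "potassium_mmol_l", list("potassium_mmol_l", 2), "age_years"))
  fit <- fit_logistic(cohort, spec)
  truth <- unclass(config$coefficients)
  est <- coef(fit)
  map <- c(glucose = "glucose_mmol_l", relvol = "rel_total", sbp = "sbp_mmhg",
           ivh = "ivh_present", potassium = "potassium_mmol_l",
           potassium_sq = "I(potassium_mmol_l^2)", age = "age_years",
           constant = "(Intercept)")
  se <- stats::setNames(fit$coefficients$se, fit$coefficients$term)
  out <- data.frame(term = names(map),
                    truth = unname(truth[names(map)]),
                    estimate = unname(est[map]),
                    se = unname(se[map]), stringsAsFactors = FALSE)
  out$bias <- out$estimate - out$truth
  out$within_3se <- abs(out$bias) <= 3 * out$se
  attr(out, "converged") <- fit$converged
  out
}
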