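#' Haematoma growth index
#'
#' A signed, bounded measure of haematoma expansion or resorption between two
#' volumetric examinations, computed on the relative-volume (haematoma per
#' brain, hpb) scale in two steps: the logit difference
#' \eqn{L = \log(hpb_2/(1-hpb_2)) - \log(hpb_1/(1-hpb_1))} and the folded
#' logistic \eqn{e^L/(1+e^L) - 0.5}. The index lies strictly in (-0.5, 0.5),
#' is zero iff the two ratios are equal, positive for expansion, negative for
#' resorption, and antisymmetric under swapping the measurements.
#'
#' A fully resorbed haematoma (`hpb2 = 0`) is undefined on the logit scale;
#' with `clip = TRUE` ratios are clamped to `[eps, 1 - eps]` with a warning
#' instead of raising an error.
#'
#' @param hpb1 baseline haematoma-per-brain ratio, strictly in (0, 1).
#' @param hpb2 second-measurement ratio, strictly in (0, 1). Vectorised.
#' @param clip clamp out-of-range ratios to `[eps, 1 - eps]` instead of
#'   erroring (default `FALSE`: strict domain check).
#' @param eps clipping bound, default 1e-6.
#' @return Growth index in (-0.5, 0.5).
#' @export
#' @examples
#' growth_index(0.012, 0.007)  # resorption, about -0.133
#' growth_index(0.01, 0.04)    # expansion, about +0.305
growth_index <- function(hpb1, hpb2, clip = FALSE, eps = 1e-6) {
  .check_number(hpb1, "hpb1")
  .check_number(hpb2, "hpb2")
  if (clip) {
    n_out <- sum(hpb1 < eps | hpb1 > 1 - eps | hpb2 < eps | hpb2 > 1 - eps)
    if (n_out > 0) {
      warning(sprintf("growth_index: %d ratio(s) clipped to [%g, %g]", n_out, eps, 1 - eps))
      hpb1 <- pmin(pmax(hpb1, eps), 1 - eps)
      hpb2 <- pmin(pmax(hpb2, eps), 1 - eps)
    }
  } else if (any(hpb1 <= 0 | hpb1 >= 1 | hpb2 <= 0 | hpb2 >= 1)) {
    .stopf("haematoma-per-brain ratios must lie strictly in (0, 1); use clip = TRUE to clamp")
  }
  L <- .logit(hpb2) - .logit(hpb1)
  .expit(L) - 0.5
}

#' Percent change between two measurements
#'
#' `100 * (v2 - v1) / v1`; negative values denote a decrease.
#'
#' @param v1 baseline value (> 0).
#' @param v2 second value (>= 0, same units). Vectorised.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(16.3, 9.3)   # about -43% (mean total volume, survivors)
#' percent_change(57.8, 89.0)  # about +54% (nonsurvivors, CT to autopsy)
percent_change <- function(v1, v2) {
  .check_number(v1, "v1", positive = TRUE)
  .check_number(v2, "v2")
  if (any(v2 < 0)) .stopf("'v2' must be >= 0")
  100 * (v2 - v1) / v1
}

#' Per-patient growth index over a cohort
#'
#' Computes `hpb1 = total_vol_cm3 / icv_cm3` and
#' `hpb2 = fu_total_vol_cm3 / ICV2` for every record and returns the cohort
#' with a `growth_index` column appended. The denominator of the second
#' ratio is controlled explicitly by `second_icv`:
#' \describe{
#'   \item{`"per_outcome"`}{the study convention — follow-up CT intracranial
#'     volume (`fu_icv_cm3`) for survivors, baseline intracranial volume
#'     (`icv_cm3`) for nonsurvivors, whose second volumetry is post-mortem
#'     and has no second CT.}
#'   \item{`"baseline"`}{always `icv_cm3`.}
#'   \item{`"followup"`}{always `fu_icv_cm3`.}
#' }
#' Records missing any required volume get `NA` (complete-case policy, count
#' reported via message).
#'
#' @param records cohort data frame in the package CSV schema.
#' @param second_icv denominator convention for the second ratio.
#' @inheritParams growth_index
#' @return `records` with a `growth_index` column.
#' @export
cohort_growth_index <- function(records,
                                second_icv = c("per_outcome", "baseline", "followup"),
                                clip = FALSE, eps = 1e-6) {
  second_icv <- match.arg(second_icv)
  icv2 <- switch(second_icv,
    per_outcome = ifelse(records$death30 %in% 1, records$icv_cm3, records$fu_icv_cm3),
    baseline = records$icv_cm3,
    followup = records$fu_icv_cm3)
  ok <- !is.na(records$total_vol_cm3) & !is.na(records$icv_cm3) &
    !is.na(records$fu_total_vol_cm3) & !is.na(icv2)
  gi <- rep(NA_real_, nrow(records))
  if (any(ok))
    gi[ok] <- growth_index(records$total_vol_cm3[ok] / records$icv_cm3[ok],
                           records$fu_total_vol_cm3[ok] / icv2[ok],
                           clip = clip, eps = eps)
  if (any(!ok))
    message(sprintf("cohort_growth_index: %d of %d records lack the volumes needed",
                    sum(!ok), nrow(records)))
  records$growth_index <- gi
  records
}
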