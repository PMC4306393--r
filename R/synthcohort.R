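# Synthetic-data generators: patient cohorts with the covariate structure of
# the learning study and outcomes drawn through the score model, and cadaver
# slice stacks cut from known ellipsoids for volumetry validation.

# moment-matched lognormal parameters for a target mean/sd
.lnorm_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# rejection-sampled truncated normal (bounds far enough out that the
# acceptance rate stays near 1 for every default used here)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n - length(out) + 16L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

.rtrunclnorm <- function(n, mean, sd, upper = Inf) {
  p <- .lnorm_pars(mean, sd)
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n - length(out) + 16L, p["meanlog"], p["sdlog"])
    out <- c(out, x[x < upper])
  }
  out[seq_len(n)]
}

#' Cohort simulation configuration
#'
#' Distributional settings for the synthetic admission cohort. The six
#' outcome-model covariates follow the learning study's pooled summary
#' statistics: age truncated normal (mean 67, SD 13, range 18--100 years),
#' systolic blood pressure normal (175/34 mm Hg), glucose lognormal
#' moment-matched to 8.1/3.9 mmol/L, potassium a three-component
#' normal mixture (normokalaemic N(4.1, 0.35) with weight 0.8, hypokalaemic
#' N(3.1, 0.3) and hyperkalaemic N(5.4, 0.5) with weight 0.1 each — the
#' survivor and nonsurvivor group means are nearly equal while the
#' nonsurvivor SD is inflated, the signature of a hypo/hyper mixture),
#' relative total haematoma volume lognormal matched to 0.027/0.027 and
#' truncated below 0.3, and intraventricular extension Bernoulli(0.416).
#' The 30-day outcome is drawn per patient through the score probability
#' under `coefficients`. Remaining schema fields (platelets 221/84 and other
#' vitals/labs, intracranial volume, compartment split, follow-up volumes)
#' are nuisance fields generated for schema completeness and do not enter
#' the outcome model. Covariates are sampled independently.
#'
#' @param n cohort size (default 125, the analysed study size).
#' @param seed RNG seed.
#' @param age,sbp,platelets,glucose list(mean, sd) for the named covariate.
#' @param potassium list of component means/sds/weights.
#' @param rel_total_volume list(mean, sd, upper).
#' @param p_ivh probability of intraventricular blood at baseline.
#' @param coefficients a [suspekt_coefficients()] object generating the
#'   outcome.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n = 125, seed = 1,
                              age = list(mean = 67, sd = 13, lower = 18, upper = 100),
                              sbp = list(mean = 175, sd = 34),
                              glucose = list(mean = 8.1, sd = 3.9),
                              potassium = list(means = c(4.1, 3.1, 5.4),
                                               sds = c(0.35, 0.3, 0.5),
                                               weights = c(0.8, 0.1, 0.1)),
                              rel_total_volume = list(mean = 0.027, sd = 0.027,
                                                      upper = 0.3),
                              p_ivh = 0.416,
                              platelets = list(mean = 221, sd = 84),
                              coefficients = suspekt_coefficients()) {
  if (n < 1) .stopf("n must be >= 1")
  if (abs(sum(potassium$weights) - 1) > 1e-8)
    .stopf("potassium mixture weights must sum to 1")
  for (s in c(age$sd, sbp$sd, glucose$sd, potassium$sds,
              rel_total_volume$sd, platelets$sd))
    if (s <= 0) .stopf("all standard deviations must be positive")
  if (p_ivh < 0 || p_ivh > 1) .stopf("p_ivh must be a probability")
  stopifnot(inherits(coefficients, "suspekt_coefficients"))
  structure(list(n = as.integer(n), seed = as.integer(seed), age = age,
                 sbp = sbp, glucose = glucose, potassium = potassium,
                 rel_total_volume = rel_total_volume, p_ivh = p_ivh,
                 platelets = platelets, coefficients = coefficients),
            class = "cohort_sim_config")
}

#' Generate a synthetic admission cohort
#'
#' Draws a cohort in the [cohort_schema()] layout from a
#' [cohort_sim_config()]. Deaths within 30 days are Bernoulli draws from the
#' per-patient score probability, so the generating coefficients are the
#' truth for [recover_parameters()]. Follow-up volumetry mirrors the study
#' design: survivors get a follow-up CT (volume shrunk by ~43% on average,
#' with a follow-up intracranial volume), nonsurvivors get post-mortem
#' volumetry (volume grown by ~54% on average, no second CT, so
#' `fu_icv_cm3` is absent and their second relative volume uses the baseline
#' intracranial volume).
#'
#' @param config a [cohort_sim_config()].
#' @return Cohort data.frame (no exclusion flags set).
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n
  age <- .rtruncnorm(n, config$age$mean, config$age$sd,
                     config$age$lower, config$age$upper)
  sbp <- stats::rnorm(n, config$sbp$mean, config$sbp$sd)
  glucose <- .rtrunclnorm(n, config$glucose$mean, config$glucose$sd)
  comp <- sample.int(3, n, replace = TRUE, prob = config$potassium$weights)
  potassium <- stats::rnorm(n, config$potassium$means[comp],
                            config$potassium$sds[comp])
  potassium <- pmax(potassium, 1.5)  # physiological floor
  relvol <- .rtrunclnorm(n, config$rel_total_volume$mean,
                         config$rel_total_volume$sd,
                         config$rel_total_volume$upper)
  ivh <- stats::rbinom(n, 1, config$p_ivh)
  b <- unclass(config$coefficients)
  sbx <- b[["glucose"]] * glucose + b[["relvol"]] * relvol +
    b[["sbp"]] * sbp + b[["ivh"]] * ivh + b[["potassium"]] * potassium +
    b[["potassium_sq"]] * potassium^2 + b[["age"]] * age + b[["constant"]]
  pr <- .expit(sbx)
  death30 <- stats::rbinom(n, 1, pr)

  # nuisance fields for schema completeness (not in the outcome model)
  icv <- .rtruncnorm(n, 1344, 130, lower = 900)
  total <- relvol * icv
  ivh_frac <- ifelse(ivh == 1, stats::rbeta(n, 2, 4), 0)
  ivh_vol <- total * ivh_frac
  # follow-up change ratios: survivors resorb, nonsurvivors expand
  change <- ifelse(death30 == 1,
                   .rtrunclnorm(n, 1.54, 0.6),
                   .rtrunclnorm(n, 0.57, 0.25))
  fu_total <- pmin(total * change, 0.35 * icv)
  fu_icv <- ifelse(death30 == 1, NA_real_, icv * stats::rnorm(n, 1, 0.015))
  fu_ivh <- ifelse(death30 == 1, stats::rbinom(n, 1, 0.881),
                   stats::rbinom(n, 1, 0.091))

  data.frame(
    patient_id = sprintf("SYN%05d", seq_len(n)),
    age_years = age,
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.55, 0.45)),
    smoker = stats::rbinom(n, 1, 0.22),
    alcohol_excess = stats::rbinom(n, 1, 0.30),
    sbp_mmhg = sbp,
    dbp_mmhg = stats::rnorm(n, 94.5, 18),
    pulse_bpm = stats::rnorm(n, 84, 15),
    sodium_mmol_l = stats::rnorm(n, 139, 4),
    potassium_mmol_l = potassium,
    glucose_mmol_l = glucose,
    hb_g_l = stats::rnorm(n, 139, 17),
    wbc_1e9_l = .rtrunclnorm(n, 9.4, 3.7),
    platelets_1e9_l = .rtruncnorm(n, config$platelets$mean,
                                  config$platelets$sd, lower = 10),
    onset_to_ct_h = .rtrunclnorm(n, 4.8, 5.5, upper = 24),
    icv_cm3 = icv,
    total_vol_cm3 = total,
    parenchymal_vol_cm3 = total - ivh_vol,
    ivh_vol_cm3 = ivh_vol,
    ivh_present = ivh,
    fu_total_vol_cm3 = fu_total,
    fu_icv_cm3 = fu_icv,
    fu_ivh_present = fu_ivh,
    death30 = death30,
    exclusion_codes = "",
    stringsAsFactors = FALSE)
}

#' Ellipsoid slice-stack simulation configuration
#'
#' Settings for cutting a synthetic cadaver slice stack from an ellipsoidal
#' haematoma of known axes: nominal slice thickness, a fixation shrinkage
#' factor applied to the achieved slice thickness (the haematoma's in-plane
#' diameters and overall extent are left unchanged — compensating shrinkage
#' is exactly why thickness is measured rather than assumed), optional
#' jitter on the four thickness readings, optional measurement noise on the
#' diameters, and the fractional offset of the haematoma's leading edge
#' within its first slice.
#'
#' @param axes ellipsoid diameters (a, b, c) in mm; `c` lies along the
#'   slicing direction.
#' @param slice_thickness nominal cutting thickness, mm.
#' @param thickness_jitter_sd SD of per-reading thickness noise, mm.
#' @param measurement_noise_sd SD of per-diameter measurement noise, mm.
#' @param shrinkage_factor achieved / nominal slice thickness, in (0.7, 1].
#' @param offset_frac position of the haematoma's leading edge within its
#'   first slice, as a fraction of the achieved thickness in \[0, 1).
#' @param seed RNG seed (used only when a noise SD is positive).
#' @return A list of class `ellipsoid_sim_config`.
#' @export
ellipsoid_sim_config <- function(axes = c(40, 30, 50), slice_thickness = 10,
                                 thickness_jitter_sd = 0,
                                 measurement_noise_sd = 0,
                                 shrinkage_factor = 1, offset_frac = 0.3,
                                 seed = 1) {
  if (length(axes) != 3 || any(axes <= 0)) .stopf("axes must be three positive diameters")
  if (slice_thickness <= 0) .stopf("slice_thickness must be positive")
  if (slice_thickness > min(axes))
    .stopf("slice thickness (%g mm) exceeds the smallest axis (%g mm)",
           slice_thickness, min(axes))
  if (shrinkage_factor <= 0.7 || shrinkage_factor > 1)
    .stopf("shrinkage_factor must lie in (0.7, 1]")
  if (offset_frac < 0 || offset_frac >= 1) .stopf("offset_frac must lie in [0, 1)")
  if (thickness_jitter_sd < 0 || measurement_noise_sd < 0)
    .stopf("noise SDs must be >= 0")
  structure(list(axes = axes, slice_thickness = slice_thickness,
                 thickness_jitter_sd = thickness_jitter_sd,
                 measurement_noise_sd = measurement_noise_sd,
                 shrinkage_factor = shrinkage_factor,
                 offset_frac = offset_frac, seed = as.integer(seed)),
            class = "ellipsoid_sim_config")
}

#' Generate a cadaver slice stack from a known ellipsoid
#'
#' Slices an ellipsoidal haematoma (diameters `axes`, the third along the
#' cutting direction) into coronal slices of achieved thickness
#' `slice_thickness * shrinkage_factor`. Each slice's haematoma diameters
#' are the exact ellipse cross-section diameters at the midpoint of the
#' slice's overlap with the haematoma:
#' \eqn{d(z) = d_{max} \sqrt{1 - (2z/c)^2}} for signed distance `z` from the
#' equator. End slices the haematoma only partially penetrates carry a probe
#' depth equal to the overlap, and interior slices carry four thickness
#' readings around the achieved thickness. The resulting stack is the ground
#' truth fixture for [cadaver_abc2()]: its true volume is
#' `abc2_volume(axes[1], axes[2], axes[3])`.
#'
#' @param config an [ellipsoid_sim_config()].
#' @return A [slice_stack()].
#' @export
generate_slice_stack <- function(config = ellipsoid_sim_config()) {
  stopifnot(inherits(config, "ellipsoid_sim_config"))
  set.seed(config$seed)
  a <- config$axes[1]; b <- config$axes[2]; cax <- config$axes[3]
  t_actual <- config$slice_thickness * config$shrinkage_factor
  z_lo <- config$offset_frac * t_actual
  z_hi <- z_lo + cax
  centre <- (z_lo + z_hi) / 2
  k <- seq(floor(z_lo / t_actual), ceiling(z_hi / t_actual) - 1)
  lo <- pmax(k * t_actual, z_lo)
  hi <- pmin((k + 1) * t_actual, z_hi)
  keep <- hi - lo > 1e-9
  lo <- lo[keep]; hi <- hi[keep]
  overlap <- hi - lo
  full <- overlap >= t_actual - 1e-9
  mid <- (lo + hi) / 2
  rel <- (mid - centre) / (cax / 2)
  shape <- sqrt(pmax(0, 1 - rel^2))
  nsl <- length(mid)
  noise <- function(sd, n) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
  diam_h <- pmax(0, a * shape + noise(config$measurement_noise_sd, nsl))
  diam_p <- pmax(0, b * shape + noise(config$measurement_noise_sd, nsl))
  th <- matrix(t_actual, nsl, 4) +
    matrix(noise(config$thickness_jitter_sd, nsl * 4), nsl, 4)
  th <- pmax(th, 0.1)
  slices <- data.frame(t1_mm = th[, 1], t2_mm = th[, 2], t3_mm = th[, 3],
                       t4_mm = th[, 4], diam_h_mm = diam_h,
                       diam_p_mm = diam_p, fully_penetrated = full)
  pf <- if (!full[1]) min(overlap[1], rowMeans(th)[1]) else NULL
  pl <- if (nsl > 1 && !full[nsl]) min(overlap[nsl], rowMeans(th)[nsl]) else NULL
  slice_stack(slices, probe_depth_first = pf, probe_depth_last = pl)
}
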