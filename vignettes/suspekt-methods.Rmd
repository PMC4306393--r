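---
title: "Methods behind the suspekt package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the suspekt package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suspekt)
```

This vignette documents the models and procedures the package implements,
the choices made where the design was genuinely open, and what the
synthetic-data machinery does and does not establish.

## The prognostic model

The SUSPEKT score is a multiple logistic regression of 30-day death after
spontaneous supratentorial intracerebral haemorrhage on six admission-time
factors: serum glucose (mmol/L), relative total haematoma volume
(haematoma / intracranial volume, unitless), systolic blood pressure
(mm Hg), presence of intraventricular blood (0/1), serum potassium
(mmol/L, entered linearly *and* squared), and age (years). The published
coefficients are embedded as `suspekt_coefficients()`; the linear predictor
is the sum of the eight coefficient×value products (`partial_products()`,
`linear_predictor()`), and the probability is the logistic transform
(`score_probability()`).

Three modelling points deserve emphasis:

* **Potassium enters quadratically on the raw scale.** The risk profile is
  U-shaped with minimum at −b₁/(2·b₂) ≈ 4.14 mmol/L, inside the normal
  range: hypo- and hyperkalaemia both predict death, plausibly through
  cardiac mechanisms rather than intracranial mass effect. The squared term
  is always derived internally from the potassium input, never accepted as
  a second independent value, so the two rows cannot disagree. No centering
  is applied before squaring, matching the published coefficient scale; the
  resulting collinearity between K and K² is handled by the fitter and
  inflates those two standard errors, which is expected and harmless for
  prediction.
* **The volume factor is the relative total haematoma volume.** An
  absolute-volume variant is argued for elsewhere on practicality grounds,
  but no absolute-volume coefficient set was ever published, so none is
  shipped; alternative coefficient files can be loaded via
  `read_coefficients()`.
* **The worked example uses rounded inputs.** The published example tabulates
  cohort-mean factor values to 3 decimals together with per-factor products;
  re-multiplying the rounded means reproduces the printed products only to
  about 0.02 (worst case the relative-volume row). The printed product
  column, whose sum is −0.2749 and whose logistic transform is 0.431706, is
  therefore shipped verbatim as `suspekt_worked_example()` and treated as
  the authoritative arithmetic; recomputation from the rounded means is
  checked at the 0.02 tolerance.

### Percentile bands

Rather than fixed probability cut-offs, the score reports where a patient
falls within the *learning cohort's* predicted-risk distribution: the 11
anchors of `suspekt_band_table()` are the minimum, the 10th–90th
percentiles, and the maximum of the model's predicted probabilities over
the learning set. `assign_band()` uses half-open lower-inclusive intervals
[anchorₖ, anchorₖ₊₁): deterministic under ties, and consistent with the
published phrasing that a probability of 0.432 lies "between" the 50th and
60th percentiles. Probabilities outside the observed range are flagged
(`below_min` / `above_max`) rather than silently clamped. When a band table
is re-derived (`build_band_table()`), the percentile method defaults to
nearest rank (the ⌈q·n⌉-th order statistic) with linear interpolation as an
option; the original statistical software's convention is unknowable, and
the shipped table is stored as constants, so this choice only affects
tables users derive themselves.

## Volumetry

`abc2_volume()` implements A·B·C/2 on mm diameters (result in cm³). The
formula approximates the ellipsoid volume π/6·ABC, so it is exactly 3/π ≈
0.955 of the exact ellipsoid volume — a property the tests verify in closed
form. Only two forms are provided: the three-diameter imaging form and the
cadaver slice-stack form; no slice-count × slice-thickness imaging variant
is offered, to avoid inventing a convention the source procedure does not
define.

For fixed post-mortem brains (`cadaver_abc2()`), A and B are the maximal
horizontal and perpendicular diameters over all slices (not necessarily the
same slice — only the magnitudes matter), and C is assembled by
`cadaver_c_axis()`: the sum of per-slice thicknesses (each the mean of four
readings, because fixation shrinks tissue and the nominal cutting thickness
overstates the achieved one) over fully penetrated slices, plus probe
depths for the end slices the haematoma only partially penetrates. A probe
depth exceeding its slice's measured thickness is a domain error. No global
shrinkage coefficient is applied anywhere: measuring actual thickness *is*
the shrinkage correction. Because parenchymal and intraventricular blood
are not reliably separable in fixed sliced brains, the cadaver estimate is
by contract the combined total. Fragmented or multilobar haematomas violate
the ellipsoid assumption; the operations still compute the formula, and
excluding such brains is a data-curation decision (`brain_unsuitable` flag)
rather than a computational one.

## The growth index

Between two volumetric examinations with haematoma-per-brain ratios hpb₁
(baseline CT) and hpb₂ (follow-up CT in survivors, post-mortem volumetry in
nonsurvivors), the growth index is expit(logit(hpb₂) − logit(hpb₁)) − 0.5:
zero iff the ratios are equal, sign equal to the direction of change,
antisymmetric, strictly monotone in each argument, and bounded in
(−0.5, 0.5). For small ratios it approaches hpb₂/(hpb₁+hpb₂) − 0.5.

The second ratio's denominator follows the study design: survivors use the
follow-up CT's intracranial volume, nonsurvivors the baseline CT's (there
is no second CT to measure). `cohort_growth_index()` makes this an explicit
`second_icv` argument (`"per_outcome"`, `"baseline"`, `"followup"`) rather
than an inference. A fully resorbed haematoma (hpb₂ = 0) is undefined on
the logit scale; how such cases were originally scored is unstated, so the
default is a strict domain error, with an opt-in `clip = TRUE` mode that
clamps ratios to [10⁻⁶, 1−10⁻⁶] under a warning. Note that a *group-mean*
growth index is a mean of per-patient indices; because the transform is
non-linear it cannot be recovered from group-mean ratios, and the package
never computes it that way.

## Refitting machinery

`fit_logistic()` maximises the Bernoulli likelihood by IRLS (tolerance
1e-8, 100 iterations) and reports Wald standard errors. Complete or
quasi-complete separation is reported as non-convergence, never as silent
estimates; it is diagnosed when fitted probabilities reach the boundary
(beyond 1−10⁻¹⁰) together with a diverging standardised coefficient norm
(|βⱼ|·sd(xⱼ) > 15, intercept excluded) and a diverging standardised
standard error — thresholds far above anything an identified fit produces
and far below the magnitudes separation produces.

The model-building workflow mirrors the original strategy:

* `univariable_screen()` fits one model per candidate, adding a squared
  term where flagged, and reports a single joint likelihood-ratio p-value
  per variable (against the intercept-only model on the same complete
  cases) — not the quadratic term's Wald test — so each variable gets one
  screening p regardless of its term count.
* `curvature_check()` decides linear vs quadratic by a 1-df LRT at a
  configurable threshold (default 0.05).
* `select_variables()` keeps variables screening below the
  "remarkable-association" threshold — undefined in the source, so it is a
  configurable parameter defaulting to 0.10 — prunes collinear pairs
  (|r| > 0.7 by default) by *user-supplied* clinical priorities (clinical
  practicability is not inferable from data), then re-offers each left-out
  variable one by one against the prefinal model.
* `hosmer_lemeshow()` groups by deciles of predicted risk and computes
  Σ(O−E)²/(E(1−E/n)) on g−2 degrees of freedom, merging tied-empty groups.
* No multiple-testing correction is applied anywhere, matching the original
  analysis; screening p-values should be read accordingly.

Missing data are handled per operation by complete-case analysis with a
reported count, reflecting that the original model was fitted on the
complete dataset.

## Synthetic data: what it emulates and what it does not

The learning cohort was never deposited, so `generate_cohort()` stands in
for it. Covariate families were chosen once to match the published group
summary statistics pooled across outcome groups: age truncated normal
(67 ± 13, 18–100 y), systolic BP normal (175 ± 34), glucose and relative
volume lognormal (positivity and right skew; moment-matched to 8.1 ± 3.9
and 0.027 ± 0.027, the latter truncated below 0.3), intraventricular
extension Bernoulli(0.416), and potassium a three-component normal mixture
— N(4.1, 0.35) with weight 0.8, hypokalaemic N(3.1, 0.3) and hyperkalaemic
N(5.4, 0.5) with weight 0.1 each — because the published group contrast is
a near-equal mean with inflated nonsurvivor spread, the signature of mixed
hypo-/hyperkalaemia. The mixture weights are free parameters whose defaults
bracket the published marginal mean/SD; no claim is made of matching the
unpublished distribution. The 30-day outcome is drawn per patient through
the score probability itself, so the generating coefficients are ground
truth for `recover_parameters()`. Remaining schema fields (sex, smoking,
alcohol, diastolic BP, pulse, sodium, haemoglobin, WBC, platelets
221 ± 84, onset-to-CT time, intracranial volume 1344 ± 130 cm³, the
compartment split, and follow-up volumes shrinking ~43% in survivors and
growing ~54% in nonsurvivors) are nuisance fields for schema completeness
and do not enter the outcome model.

Covariates are generated independently: no covariance structure was ever
published, and inventing one would manufacture spurious realism. This is
the generator's main limitation — passing tests demonstrate that the
scoring arithmetic, the fitting machinery and the recovery pipeline are
correct *under independence*, not that the score generalises to real
correlated clinical data; age–blood-pressure or volume–IVH dependence,
measurement error, and informative missingness are all absent.

`generate_slice_stack()` cuts a synthetic cadaver stack from an ellipsoid
of known axes: per-slice diameters are exact ellipse cross-sections at the
midpoint of each slice's overlap with the haematoma, end slices carry probe
depths equal to their overlap, and thickness readings equal the achieved
thickness (nominal × shrinkage factor) plus optional jitter. Because the
measured-thickness sum always spans the true extent, the recovered volume
is invariant to the shrinkage factor by construction — which is precisely
the argument for measuring thickness rather than assuming it. Noise-free
stacks let the tests quantify pure discretisation error: about 1–4% at
10 mm slices for a 40×30×50 mm haematoma, under 2% at 1 mm.

## Numerical and validation choices

* The logistic transform uses the symmetric stable form, exact for
  |sbx| ≤ 700 and graceful beyond.
* Band lookups, percent changes and the worked example are deterministic;
  every stochastic test fixes its seed.
* Problem sizes were chosen to make Monte-Carlo checks sharp but quick:
  moment checks at n = 60 000 against the analytic means of the actually
  sampled (truncated) distributions with 3-standard-error tolerances;
  type-I error of the univariable screen at 1000 replicates of n = 150
  (binomial SE ≈ 0.7%, tested against 5% ± 1.5%); parameter recovery at
  n = 5000 with a ±3-standard-error criterion for all eight coefficients.
* The exclusion-count arithmetic of the original cohort (which of 156
  admissions reached the analysed 125) is treated as data, never
  hard-coded: the two published survivor/nonsurvivor tallies disagree with
  each other, and the package takes no side — `apply_exclusions()` simply
  filters whatever flags the data carry and audits every removal.

## Known limitations

* The published per-patient data being unavailable, the original Tables'
  p-values and group contrasts are not reproducible; the package validates
  direction-of-effect and recovery properties instead.
* The cadaver volumetry contract is total-volume only; compartment splits
  at autopsy are out of scope.
* `select_variables()` automates a strategy that originally involved
  clinical judgement; the priority vector is the user's clinical input, not
  a statistical estimate.
* The score awaits external validation; nothing here should be read as a
  treatment-decision rule.
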