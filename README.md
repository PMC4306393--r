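# suspekt

Prognostic modelling after spontaneous supratentorial intracerebral
haemorrhage (ICH). The package is aimed at stroke researchers and
biostatisticians who need to (a) score patients with the six-factor
**SUSPEKT** model for 30-day mortality, (b) estimate haematoma volumes with
the ABC/2 method — from CT diameters or from post-mortem coronal brain
slices — and (c) rebuild or validate the score on their own cohorts.

## The model

SUSPEKT is a multiple logistic regression model of death within 30 days
with six admission-time factors: serum glucose (**SU**gar), relative total
haematoma volume (**S**ize), systolic blood pressure (**P**), presence of
intraventricular blood (**E**xtension), serum potassium (**K**alium,
entering both linearly and squared), and age (life**T**ime). For a patient
with factor vector *x*,

    sbx = b·x + constant,      pr = e^sbx / (1 + e^sbx)

where `b` is the published coefficient vector (potassium² computed
internally from potassium). The quadratic potassium term makes predicted
risk U-shaped with a minimum near 4.14 mmol/L: both hypo- and
hyperkalaemia raise the predicted odds of death. The probability `pr` is
then referred to an 11-anchor percentile band table (minimum, 10th…90th
percentile, maximum of the learning cohort's predicted probabilities), so a
new patient is reported as lying between two learning-set percentiles.

Around the score the package provides:

* **Volumetry** — `abc2_volume()` (A·B·C/2, mm³→cm³), `cadaver_abc2()` for
  fixed-brain slice stacks (averaged four-point slice thicknesses summed
  into the C axis, probe depths for partially penetrated end slices), and
  `relative_volume()` (haematoma / intracranial volume).
* **Dynamics** — `growth_index()`, the bounded logit-difference statistic
  `expit(logit(hpb2) − logit(hpb1)) − 0.5` in (−0.5, 0.5), and
  `percent_change()`.
* **Inference** — `fit_logistic()`, `univariable_screen()` (joint LRT with
  optional quadratic terms), `curvature_check()`, `select_variables()`
  (remarkable-association threshold, collinearity pruning by supplied
  clinical priority, one-by-one add-back), `hosmer_lemeshow()` calibration
  and `recover_parameters()`.
* **Synthetic data** — `generate_cohort()` (covariates matched to the
  learning study's summary statistics, outcome drawn through the score) and
  `generate_slice_stack()` (slices cut from a known ellipsoid, with
  fixation-shrinkage and measurement-noise controls).

## Worked example

```r
library(suspekt)
score_patient(list(glucose = 12.4, rel_total_volume = 0.061, sbp = 190,
                   ivh = 1, potassium = 5.6, age = 74))
#> SUSPEKT score
#>      glucose       relvol          sbp          ivh    potassium potassium_sq
#>     1.308250     4.205808     0.578170     0.441198  -108.034640    73.056476
#>          age     constant
#>     2.964218    33.542280
#> linear predictor (sbx): 8.061759
#> probability of 30-day death (pr): 0.999685
#> risk band: between the 90th and maximum learning-set percentiles [0.975373, 0.999965)
```

The eight numbers are the per-factor coefficient×value products (potassium
pulls the predictor down, its square pushes it back up); their sum is the
linear predictor `sbx`, the logistic transform of `sbx` is the predicted
probability of death within 30 days, and the band line places that
probability within the learning cohort's risk distribution — here a
hyperglycaemic, hypertensive, hyperkalaemic 74-year-old with a large
haematoma and ventricular extension sits above the 90th percentile.

The model object interface mirrors classic R modelling packages:

```r
m <- suspekt_model()                    # published coefficients + bands
predict(m, generate_cohort(cohort_sim_config(n = 100, seed = 1)))
m2 <- fit_suspekt(my_cohort)            # refit the six-factor model
summary(m2); plot(m2); residuals(m2)
```

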