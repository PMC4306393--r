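Package: suspekt
Title: Six-Factor Prognostic Score and Volumetry for Supratentorial
    Intracerebral Haemorrhage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for 30-day mortality prognosis after spontaneous
    supratentorial intracerebral haemorrhage: ABC/2 haematoma volumetry
    from imaging diameters and from post-mortem coronal slice stacks,
    relative haematoma volumes, a logit-difference haematoma growth
    index, the six-factor SUSPEKT logistic score (glucose, relative
    haematoma volume, systolic blood pressure, intraventricular
    extension, potassium with a quadratic term, age) with percentile-band
    risk reporting, logistic refitting machinery with curvature checks,
    variable selection and Hosmer-Lemeshow calibration, and synthetic
    cohort and cadaver slice-stack generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
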