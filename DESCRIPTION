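Package: bpvpoincare
Title: Intraoperative Blood Pressure Variability by Poincare Descriptors
    and Coefficient of Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Phase-segmented analysis of intraoperative blood pressure (BP)
    time series from cardiac surgery with cardiopulmonary bypass. Computes
    lag-1 Poincare plot descriptors SD1/SD2 via the ellipse-fitting
    construction and the coefficient of variation per surgical phase and
    pressure channel, applies cohort exclusion filters, builds per-patient
    BP-variability feature rows, and evaluates univariable and
    covariate-adjusted logistic outcome models by C-statistic (with
    DeLong-style confidence intervals) and Hosmer-Lemeshow calibration.
    Includes a synthetic-cohort generator with phase-structured AR(1) BP
    dynamics and logistic outcomes so the whole chain runs and is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
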