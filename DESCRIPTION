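Package: keraprog
Title: Forecasting Keratoconus Progression from Longitudinal Corneal Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to detect and forecast progressive trends in keratoconus
    from short, irregularly spaced series of Scheimpflug corneal tomographies.
    Exam series are decomposed into sliding triplets of three consecutive
    examinations; each triplet is labelled stable or suspect progressive by a
    repeatability-based minimally-detectable-change rule (r = 1.96 * sqrt(2) * Sw),
    denoised with a direction-aware three-branch shrinkage, and the third exam
    is forecast from the first two with a time-delay neural network trained by
    Levenberg-Marquardt. Includes a synthetic-cohort generator with known
    ground truth, a repeated-retrain evaluation protocol (sensitivity,
    specificity, PPV, NPV), Wilcoxon comparison of data-quality policies, and
    Bland-Altman agreement summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'shared.R'
    'repeatability.R'
    'cohort.R'
    'io.R'
    'triplets.R'
    'tdnn.R'
    'evaluation.R'
    'pipeline.R'
    'keraprog-package.R'
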