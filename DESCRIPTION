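Package: phenoscreen
Title: Passive Smartphone Sensing Features and Mental Health Screening Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital-phenotyping analysis of passively collected smartphone
    sensor streams. Extracts eight behavioral features per subject from a
    14-day observation window (diurnal regularity of ambient-audio volume,
    speech presence, weeknight sleep disturbance, death-related word usage,
    GPS-derived locations visited and exits from home, screen use, and time
    in darkness), screens subjects for social anxiety, generalized anxiety,
    and depression from LSAS, GAD-7, and PHQ-8 self-report scores, and
    evaluates logistic-regression screening models with repeated k-fold
    cross-validation, AUROC, and the corrected resampled t-test. Includes a
    synthetic cohort generator with known ground truth so the full pipeline
    is testable without access to raw participant data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
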