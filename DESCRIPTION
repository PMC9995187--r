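Package: flutterppi
Title: Atrial Flutter Mechanism Discrimination from P-to-P Interval Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noninvasive discrimination of the atrial flutter mechanism (focal
    versus macroreentrant) from the variability of P-to-P interval series
    measured on the 12-lead surface ECG. Provides interval-series handling and
    filtering, three minority-class data-augmentation samplers (SMOTE, a
    variance-corrected modified SMOTE, and the smoothed bootstrap), a
    four-test battery validating augmented data against the original
    distribution, descriptive-statistics feature extraction, filter
    (Wilcoxon rank-sum) and exhaustive wrapper feature selection, linear
    classifier evaluation (LDA, logistic regression, linear SVM) with grouped
    stratified cross-validation, best-augmentation-rate selection, and a
    synthetic cohort generator so the full pipeline is testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
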