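Package: vfqr
Title: Rasch-Based Scoring and Psychometric Evaluation for the NEI VFQ
    Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the 25-item National Eye Institute Visual Functioning
    Questionnaire (NEI VFQ-25) under its classical 0-100 conventions and
    implements the revised 28-item, two-domain, Rasch-scored NEI VFQ-28-R:
    item-set revision (exclusions, Appendix additions, response-level
    collapsing, 'not sure' recoded to missing) and person measurement under
    the partial credit model. Ships the complete Rasch Measurement Theory
    evaluation toolkit used to justify the revision: scale-to-sample
    targeting, threshold ordering, item fit (fit residuals and item-trait
    chi-square), differential item functioning by ANOVA of standardized
    residuals, local dependence via residual correlations, and the person
    separation index. Includes joint maximum-likelihood calibration and a
    synthetic-respondent simulator emulating a ceiling-shifted clinical
    trial population for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
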