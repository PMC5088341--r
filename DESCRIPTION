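Package: emalapse
Title: Real-Time Smoking Lapse Risk Estimation from Ecological Momentary
    Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating momentary smoking-lapse risk
    estimators from ecological momentary assessment (EMA) data collected during
    the first week of a quit attempt. Implements the full analysis pipeline:
    validated delimited-text input/output for EMA records and participant
    rosters, a seeded synthetic cohort generator that reproduces the sampling
    design and group-conditional risk-factor prevalences of the motivating
    study, lapse-proximity windowing (imminent lapse defined as within 4 hours
    of the first lapse), dichotomization of six momentary risk factors into an
    unweighted 0-6 count score and a weighted linear risk score, exhaustive
    grid search over item weights to maximize joint sensitivity and
    specificity, and ROC-based evaluation with AUC confidence intervals,
    correlated-ROC comparison, operating points, participant-level detection
    rates, and mixed-effects group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    pROC,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
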