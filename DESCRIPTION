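Package: pvmine
Title: Pharmacovigilance Signal Mining and Risk-Factor Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An integrated pipeline for mining spontaneous adverse-event
    reporting data of the FAERS ("$"-delimited quarterly ASCII) dialect:
    report deduplication and primary-suspect selection, four-algorithm
    disproportionality signal detection (reporting odds ratio, proportional
    reporting ratio, Bayesian confidence propagation information component,
    and the DuMouchel multi-item gamma-Poisson shrinker), Weibull
    time-to-onset hazard characterization, and a two-stage risk-factor
    analysis (univariate screen, LASSO selection with the one-standard-error
    rule, multivariable logistic regression) applicable to both
    case/non-case report data and clinical cohorts.  A seeded synthetic-data
    generator produces FAERS-like report tables and cohort tables with known
    planted structure so every stage is testable without access to the
    source databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
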