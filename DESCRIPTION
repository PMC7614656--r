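Package: compositemi
Title: Missing-Data Methods for Binary Composite Endpoints with Partially
    Observed Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing a binary composite endpoint whose components
    are partially (and non-simultaneously) missing in randomized trials.
    Provides a closed-form bias analysis of the "derived endpoint" strategy
    when one of two components is missing completely at random, a saturated
    log-linear data-generating model for correlated binary components with
    calibration to target arm event rates, logistic missingness mechanisms,
    three-valued evaluation of monotone composite definitions, multiple
    imputation at the composite and component level (chained equations with
    passive composite imputation, stratified conditional models, and weighted
    pseudo-observation augmentation against perfect prediction), Rubin's-rules
    pooling, a factorial simulation harness with Monte Carlo performance
    measures, and a block-based pipeline for composites built from repeated
    daily assessments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
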