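Package: qolnorm
Title: Population Norms for Health-Related Quality of Life via
    One-Inflated Beta Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating age-specific population norms of
    health-related quality-of-life from general-population surveys using
    the EQ-5D-3L descriptive system and a visual analogue scale (VAS).
    Provides tariff-based EQ-5D index scoring, boundary-avoiding outcome
    transforms, fully conditional specification multiple imputation with
    predictive mean matching, maximum-likelihood beta and one-inflated
    beta regression with randomized quantile residual diagnostics,
    two-step backward elimination and AIC-guided factor recategorization,
    bootstrap variance estimation pooled across imputations with Rubin's
    rules, and age-gridded norm curves with bootstrap confidence bands.
    A synthetic cohort generator with known ground-truth coefficients
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    nnet,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
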