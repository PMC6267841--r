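Package: mcpwr
Title: Sample Size and Power for Multi-Centre Trials with Block Randomisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sample size determination and Monte-Carlo power assessment for
    two-arm multi-centre randomized trials that use centre-stratified
    permuted-block randomisation and are analysed with a random-intercept
    linear model. Provides the exact conditional distribution of the squared
    treatment imbalance arising in incomplete randomisation blocks, four
    closed-form sample size formulas (lower boundary, equal centres, unequal
    centres, upper boundary), a trial simulator with several subject-to-centre
    allocation schemes, moment estimators for the variance components, the
    normal-approximation Wald test, and a simulation engine for empirical
    power and type-I error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
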