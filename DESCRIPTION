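Package: prepostsim
Title: Monte Carlo Simulation of Pre-Post Intervention Designs with
    Measurement Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for evaluating regression analyses of
    treatment success in two-group pre-post intervention studies (for
    example cognitive training trials). Generates true scores from a
    calibrated generative model, imposes classical-test-theory measurement
    error at configurable reliability, fits the five canonical predictor
    sets (external predictors, pre-test score, group, predictor-by-group
    interactions) against four criterion variables (post-test, absolute
    change, relative change, residualized change), and aggregates power,
    type-I-error rates, coefficient distributions and studentized bias
    over a factorial grid of sample sizes and reliabilities. Also verifies
    the closed-form identities linking post-test and change-score
    regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
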