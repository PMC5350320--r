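Package: kinspec
Title: Kinetic Spectrophotometric Quantitation by Fixed-Time, Initial-Rate
    and Rate-Constant Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for kinetic spectrophotometric
    assays in which an analyte is quantified through the absorbance of a
    reaction product (Beer-Lambert detection of a pseudo-nth-order
    product-formation curve). Provides a seeded synthetic-data generator for
    absorbance-time traces, reagent blanks, calibration sets and
    design-of-experiments response tables; the three classical kinetic
    quantitation methods (initial rate, rate constant, fixed time) with a
    formal fixed-time selection rule; reaction order and rate estimation from
    log-log regression; limit-logarithmic stoichiometry; two-level factorial
    screening and circumscribed central composite response-surface
    optimization; and full analytical validation statistics (blank sigma,
    LOD/LOQ, linear range, recovery, intraday/interday precision, bias
    t-tests). All user-facing functions take data frames and return tibbles;
    fitted objects have tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
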