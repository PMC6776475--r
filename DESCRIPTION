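Package: freesugar
Title: Stepwise Sugar Composition Databases and Free Sugar Intake Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds total, added and free sugar food-composition databases by
    ordered stepwise imputation rules with full step provenance, estimates
    daily sugar intake from 3-day weighed dietary records of young children,
    classifies excessive free sugar intake against the WHO 10 percent-of-energy
    threshold, and analyses associations between excessive intake and child,
    parental and household characteristics with crude and multivariable
    logistic odds ratios. Includes a calibrated synthetic-data generator so
    the whole pipeline is testable without access to individual-level survey
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
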