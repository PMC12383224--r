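Package: moralcan
Title: Moral-Dilemma Decision Parameters: Traditional, Process-Dissociation,
    CNI and CAN Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing responses to 2x2 moral-dilemma batteries
    (proscriptive/prescriptive norm by benefits/costs) under four measurement
    frameworks: the traditional utilitarian acceptance score, the
    process-dissociation U/D decomposition, the CNI multinomial processing
    tree fitted by maximum likelihood with G-squared fit assessment, and the
    algebraic CAN decomposition on binary or continuous ratings. Includes
    Perceived Stress Scale and social-desirability scoring, participant
    screening, covariate-adjusted correlations with Cohen's d and power
    conversions, a synthetic-cohort generator with configurable
    stress-to-parameter coupling, and simulation studies of dichotomization
    Type I error and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
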