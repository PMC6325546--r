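Package: tojlab
Title: Analysis Pipeline for Visual Temporal-Order-Judgment Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-alternative visual
    temporal-order-judgment (TOJ) psychophysics: signal-detection d-prime
    under a half-scaled z convention with extreme-proportion corrections,
    group-level logistic psychometric-function fitting with 75% JND
    threshold extraction, median-statistic Monte Carlo permutation tests
    for pairwise group differences and a 2x2 within-participant
    interaction, Lilliefors normality screening, reaction-time median and
    rank-correlation analyses, exact-binomial inclusion screening, tempo
    and rotation-angle conversions, and a synthetic-observer simulator
    that reproduces the trial structure the analyses assume.
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
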