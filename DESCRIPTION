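Package: varGxE
Title: Variance Polygenic Scores and Matched Difference-in-Differences
    for Gene-by-Environment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying genetic moderation of environmental shocks
    on body-mass index using variance polygenic scores (vPGS). Implements
    polygenic score construction with allele alignment and greedy LD
    clumping, a double generalized linear model (DGLM) relating a score to
    between-individual phenotype variance, a per-variant dispersion scan,
    probit propensity scores with Epanechnikov kernel matching and balance
    diagnostics, weighted difference-in-differences regression with
    genotype interactions and robust standard errors, treatment-effect
    prediction by genotype, Benjamini-Hochberg false discovery rate
    control, and event-time-study pre-trend diagnostics. A synthetic
    cohort generator with known genetic architecture, confounded
    treatment assignment, and a biennial BMI panel makes every stage
    testable end to end.
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
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
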