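Package: mrmediate
Title: Two-Sample Mendelian Randomisation with Maternal Effect
    Partitioning and Two-Step Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation of maternal
    exposures on pregnancy outcomes. Reads, filters, clumps and harmonises
    GWAS summary statistics into instrument sets; partitions duo
    (maternal/fetal) GWAS effects into maternal-specific effects with the
    weighted linear model; fits an estimator panel (inverse-variance
    weighted with multiplicative random effects, MR-Egger, weighted
    median, simple and weighted mode) with Cochran's Q and instrument
    strength diagnostics; performs two-step MR mediation with
    product-of-coefficients indirect effects and delta-method standard
    errors; and simulates GWAS summary statistics with known causal
    structure, horizontal pleiotropy and mother-child allele sharing so
    the whole pipeline is testable against ground truth.
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
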