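Package: cgwas
Title: Combining Correlated Genome-Wide Association Studies from Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines K correlated single-trait genome-wide association
    studies (GWAS) into one genome-wide vector of p-values testing the null
    of no effect on any trait, using only summary statistics. Implements
    effect-based inverse covariance weighting (EbICoW) with an iterative
    pairwise combination algorithm, a per-variant truncated Wald test over
    a grid of p-value thresholds, and an empirical calibration layer
    (effective-test-number estimation, Tippett adjustment and quantile
    coefficients) that makes the final p-values uniform under the null
    for any background-correlation structure. Also provides LD-free
    estimators of per-study inflation, background correlation and effect
    correlation, a summary-statistics simulator with controlled effect
    patterns and sample overlap, and post-hoc statistics (multi-trait
    effect score, power-gain ratio, Fisher's combined replication test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
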