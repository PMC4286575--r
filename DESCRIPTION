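Package: twinextremes
Title: Twin and Sibling Analysis of High-Scoring Extreme Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of extreme-group (high-scoring)
    phenotypes from twin and sibling pair data. Provides a synthetic-cohort
    simulator for polygenic liability under the ACE model with stanine
    discretisation and birth-year drift; probandwise and pairwise concordance;
    maximum-likelihood tetrachoric correlations; liability-threshold and
    continuous ACE variance decomposition with profile-likelihood confidence
    intervals and submodel comparison; and DeFries-Fulker extremes regression
    with group heritability and bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mvtnorm,
    pracma,
    MASS,
    ggplot2
Config/testthat/edition: 3
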