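Package: causalmix
Title: Constraint-Based Causal Discovery for Mixed Data with Missing Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Causal structure learning for observational data that mix
    discrete and continuous variables and contain missing entries. Variables
    are mapped to Gaussian normal scores through the rescaled empirical
    distribution (a Gaussian-copula / nonparanormal transform), the
    correlation matrix is estimated under a missing-at-random assumption by
    expectation maximization, and a Bayesian constraint-based search scores
    all directed acyclic graphs on small variable subsets to attach posterior
    reliabilities to causal statements, returning a partial ancestral graph
    with per-edge reliabilities. Comparison estimators (pairwise, listwise
    and mean-imputed Spearman correlation, with or without the Gaussian
    adjustment), a reference PC algorithm, and a conditional-Gaussian
    benchmark simulator (the Waste Incinerator network) with monotone
    distortion and missingness injection are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
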