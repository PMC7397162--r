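Package: ibcfgs
Title: Item-Based Collaborative Filtering for Multi-Trait, Multi-Environment
    Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Phenotype prediction for plant breeding trials using an item-based
    collaborative filtering (IBCF) recommender: trait-environment combinations
    are treated as items, lines as users, and missing phenotypes are imputed as
    similarity-weighted averages of each line's standardized records. Includes
    marker-based trait adjustment by Bayesian whole-genome regression (Bayesian
    ridge, BayesA/B/C, Bayesian LASSO) via Gibbs sampling, a GBLUP baseline with
    a VanRaden genomic relationship matrix and spectral REML, cross-validation
    scenarios for next-season, multi-environment, secondary-trait and
    marker-adjusted prediction, evaluation metrics (predictive ability, MAAPE,
    RMSE, genetic correlation), and a synthetic multi-environment trial
    generator with controlled heritability and between-environment genetic
    correlation.
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
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
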