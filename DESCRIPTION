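Package: spectrakin
Title: Milk FTIR, On-Farm and Genomic Prediction of Blood Metabolic
    Indicators in Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates milk Fourier-transform infrared (FTIR) spectra with
    on-farm covariates (days in milk, parity) and SNP genotypes to predict
    blood indicators of metabolic disorders in dairy cows. Provides spectral
    preprocessing and Mahalanobis outlier screening, SNP and sample quality
    control, pedigree (A), genomic (G) and single-step (H inverse)
    relationship matrices, a Gibbs sampler for the single-step GBLUP animal
    model with posterior heritability and batch incidence, a BayesB
    whole-spectrum/whole-genome regression sampler with a point-mass plus
    scaled-t mixture prior, gradient-boosted trees with random hyperparameter
    search and split-improvement variable importance, and tenfold, batch-out
    and herd-out cross-validation with predictive-ability statistics. A
    synthetic-data module emulates the layered structure of a two-herd dairy
    population so the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
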