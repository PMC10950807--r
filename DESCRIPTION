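Package: circuitshap
Title: Explainable Drug-Target Prioritization on Mechanistic Signaling Circuit Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the expression of known drug targets (KDTs) to mechanistic
    disease-map circuit activities with a multi-output random forest, explains
    the fitted map with exact interventional Shapley attributions, and distills
    a signed KDT-by-circuit relevance matrix (the repurposing profile) gated by
    per-circuit predictive R2 and quantile selection. Model quality is reported
    as bootstrap-resampled R2 and Nogueira selection-stability estimates with
    95% confidence intervals. Includes disease-definition file parsing, circuit
    map assembly from seed genes or disease identifiers, kNN imputation,
    successive-halving hyperparameter search, drug-level ranking, and
    publication-ready stability and relevance figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
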