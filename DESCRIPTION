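Package: metabnet
Title: Metabolite-Metabolite Association Networks and Differential
    Connectivity for Serum Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated statistical and network analysis pipeline for
    targeted serum metabolomics cohorts with several clinical groups:
    PCA-ellipse outlier screening, rank-based inverse normal (Blom)
    normalisation, per-metabolite Student's t-tests with Benjamini-Hochberg
    control, resampled random-forest classification with permutation
    significance, PCLRC (probabilistic context likelihood of relatedness on
    correlation) inference of group-specific metabolite-metabolite
    association networks, permutation-based differential connectivity
    analysis, NetworkAnalyzer-style topology metrics with PCA comparison,
    and hypergeometric pathway over-representation with an impact-score
    filter. Includes a synthetic-cohort generator with planted correlation
    blocks and mean shifts so every stage can be validated against a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
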