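Package: shaperobust
Title: Genetics of Shape Robustness: Canalization and Developmental
    Stability of Landmark Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of mean shape, canalization, and developmental
    stability for 3D landmark data with object symmetry. Provides generalized
    Procrustes superimposition with symmetric/asymmetric (fluctuating
    asymmetry) decomposition, genotype-conditional residual shape distances,
    leave-one-chromosome-out linear-mixed-model genome scans with permutation
    thresholds, a marginal-epistasis variance-component score test with
    weighted chi-square (Davies-type) p-values and pairwise interaction
    follow-up, REML estimation of G/E/P/FA covariance matrices with the
    multivariate heritability spectrum, Krzanowski common-subspace and other
    covariance-matrix comparisons, epistatic-network construction with
    centrality and enrichment statistics, and a synthetic-cohort generator
    with full ground truth for parameter-recovery studies.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
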