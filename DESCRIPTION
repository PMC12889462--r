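Package: wormagg
Title: Quantifying Collective Aggregation Behavior in C. elegans and Its
    Evolutionary Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify aggregation behavior of Caenorhabditis
    elegans from multi-worm video recordings and to relate the resulting
    traits to environment and genotype. Implements graph-based cluster-size
    estimation (temporal blob graphs, iterative single-worm classification,
    conservation-constraint size propagation with interval bounding),
    inverse-spatial-entropy aggregation magnitude A(t), integral-timescale
    temporal persistence tau_A, and an evolutionary statistics layer:
    phylogenetic generalized least squares with Brownian covariance and AIC
    subset selection, maximum-likelihood population effects (MLPE) models on
    pairwise distance matrices with AICc selection, VanRaden genomic
    relationship matrices, REML heritability, and two-random-effect QTL
    variance partitioning. A synthetic-data module simulates aggregating
    worms with known ground truth so the full pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    lme4,
    nlme,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
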