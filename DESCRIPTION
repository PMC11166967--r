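Package: spacederm
Title: Multi-Mission Spaceflight Skin Transcriptomics Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable reimplementation of a multi-mission rodent
    skin transcriptomics meta-analysis workflow: per-subset negative-binomial
    Wald differential expression with median-of-ratios normalization and
    trended dispersion shrinkage, cross-mission consensus gene calling and
    upset summaries, hypergeometric over-representation and weighted
    running-sum gene-set enrichment with a permutation null, high-variance
    gene filtering with 2-D embedding and density-based gene-module
    clustering, an interpretable two-gene synergy classifier search with AUC
    ranking and decision boundaries, and signed upstream-regulator activation
    z-scores. A synthetic multi-mission count-data generator with planted
    effects and a matching truth table drives recovery benchmarking of every
    stage.
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
    grDevices,
    MASS,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    uwot,
    yaml
Suggests:
    DESeq2,
    fgsea,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
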