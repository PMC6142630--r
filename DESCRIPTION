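Package: hoxcombo
Title: Combinatorial Hoxd Expression Analysis in Single Limb Bud Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for dissecting heterogeneous,
    combinatorial activation of the posterior Hoxd genes (Hoxd9-Hoxd13) in
    single-cell RNA-seq of the developing mouse limb. Provides quality-control
    filters for cells and genes, ERCC spike-in size-factor normalization with
    per-batch mean centering and gene-length correction, a dual-threshold
    per-cell combination caller, empirical-Bayes moderated two-group
    differential expression, Spearman covariance analysis against the Hoxd
    panel with hierarchical clustering, spike-calibrated highly-variable-gene
    selection and tSNE embedding, diffusion maps with diffusion pseudo-time
    and combination-group centroids, a marker-pair cell-cycle scorer, quadrant
    gating for two-channel RNA flow cytometry, and a synthetic-data generator
    that emulates the nested-activation structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    mclust,
    optparse,
    scran,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
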