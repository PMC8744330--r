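Package: senescape
Title: Tissue-Wide Co-Expression Landscapes of Cellular Senescence Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for mapping the co-expression landscape of cellular
    senescence genes (SnGs) across tissues. Bulk count matrices are filtered,
    TMM-normalized, log2-transformed and residualized against technical and
    demographic covariates; tissue-specific unsigned co-expression networks are
    built by FDR-filtered Pearson correlations grown into planar maximally
    filtered graphs (PMFG), with multiscale module detection and hub calling;
    modules are scored by Fisher's exact enrichment (with Benjamini-Hochberg
    correction), module eigengenes and Spearman age correlation; SnG-enriched
    modules feed a binary presence matrix clustered by consensus k-means,
    conservation-weighted network aggregation and seed-gene consensus
    neighborhoods. Single-cell and spatial validation statistics include
    log-normalization, Louvain clustering, Wilcoxon marker detection, per-cell
    and per-voxel permutation GSEA, coexistence-proportion tests and
    ligand-receptor communication permutation tests. A synthetic-data module
    generates every input with planted structure so the whole pipeline runs
    offline and is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    edgeR,
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    withr
Config/testthat/edition: 3
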