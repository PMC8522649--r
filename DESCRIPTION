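Package: mstx
Title: Morphometric Similarity Networks and Imaging Transcriptomics
Version: 0.1.0
Authors@R:
    person("mstx", "maintainers", email = "maintainers@mstx.dev", role = c("aut", "cre"))
Description: End-to-end analysis of case-control differences in cortical
    morphometric similarity (MS) networks and their association with spatial
    gene expression. Builds per-subject MS matrices from multimodal regional
    MRI features (after empirical-Bayes batch harmonization and within-subject
    z-scoring), computes regional weighted degree, fits covariate-adjusted
    regional group contrasts with FDR control, relates the resulting T map to
    a regions-by-genes expression matrix by first-component partial least
    squares with bootstrap gene Z scores, and screens the thresholded gene
    sets for enrichment in differentially expressed genes, cell-type-specific
    genes (specificity index), and arbitrary gene-set collections. Ships a
    synthetic-data generator with planted ground truth so the whole pipeline
    is testable without access to cohort or atlas data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
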