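Package: cx3sig
Title: Consensus Core-Signature Derivation for CX3CR1+ Cytotoxic Memory CD8+ T Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A consensus pipeline for deriving a core gene and protein
    signature of cytotoxic (CX3CR1+) memory CD8+ T cells from transcriptome
    and proteome profiles of five sorted T-cell populations. Implements
    median-of-ratios count normalization with flooring, present/variable
    gene filtering, per-gene ANOVA differential expression with
    Benjamini-Hochberg correction, three clustering engines (Markov
    clustering of Pearson correlation graphs, weighted correlation network
    module detection with eigengene merging, and self-organizing maps),
    effector-cluster selection, signature refinement, label-free proteomics
    filtering and downshifted-normal imputation, cross-omics matching and
    overlap, hypergeometric gene-set enrichment, and enrichment-map network
    construction. Ships a seeded synthetic-data generator with planted
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    igraph,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
biocViews: Transcriptomics, Proteomics, GeneExpression, Network, Clustering,
    DifferentialExpression, GeneSetEnrichment
Collate:
    'cx3sig-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'config.R'
    'io.R'
    'synthetic.R'
    'preprocess.R'
    'diffexpr.R'
    'netclust-graph.R'
    'netclust-som.R'
    'netclust-wcna.R'
    'signature.R'
    'goea.R'
    'pipeline.R'
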