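Package: starrkit
Title: Quantitative Enhancer Activity Analysis for UMI-Tagged STARR-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of massively parallel reporter
    assays of the STARR-seq family in which reporter transcripts carry unique
    molecular identifiers (UMIs). Covers UMI-aware deduplication of reporter
    fragments (exact and directional modes), normalized STARR activity scores,
    enhancer calling against an input-library background with replicate and
    fragment-support filters, differential activity between culture conditions,
    AME-style motif enrichment with background subsampling, construction and
    scanning of nuclear-receptor repeat variants (DR/IR/ER, spacers 0-8),
    sequence-based activity classification by elastic-net logistic regression
    with nested cross-validation, and k-means chromatin-state clustering of
    histone-modification profiles. A seeded synthetic-data generator with full
    ground truth supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    data.table,
    glmnet,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: FunctionalGenomics, GeneRegulation, Sequencing, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chromatin.R'
    'classifier.R'
    'dedup.R'
    'demo-pipeline.R'
    'differential.R'
    'genome-io.R'
    'genome-ops.R'
    'motif-composite.R'
    'motif-enrich.R'
    'motif-scan.R'
    'quantify.R'
    'synth-config.R'
    'synth-genome.R'
    'utils.R'
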