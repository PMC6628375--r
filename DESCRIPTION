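Package: melanolnc
Title: Long Non-Coding RNA Expression Analysis for Canine Oral Melanoma Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for profiling long non-coding RNAs in
    matched normal/tumor bulk RNA-seq cohorts, developed around canine oral
    mucosal melanoma. Provides negative-binomial GLM differential expression
    with cell-type enrichment covariates and normal-prior log-fold-change
    shrinkage, rank-based single-sample cell-type scoring, signed weighted
    co-expression networks with module-eigengene/trait statistics and hub
    extraction, cross-species lncRNA orthology from spliced alignments via
    CIGAR identity and strand-aware split exon intersection, hypergeometric
    over-representation with guilt-by-association transfer to lncRNAs, and a
    seeded synthetic-cohort generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    optparse
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Network, GeneSetEnrichment, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
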