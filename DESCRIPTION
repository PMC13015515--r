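Package: lionessRT
Title: Individualized Replication-Timing and RNA Coexpression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene coexpression networks that integrate a
    replication-timing proxy derived from promoter DNA methylation, derives
    patient-specific networks with the LIONESS leave-one-out identity, scores
    gene modules per patient, and classifies basal-like versus classical
    pancreatic ductal adenocarcinoma with a logistic readout, optionally
    modulated by whole-slide-image morphology embeddings. Includes permutation
    nulls, bootstrap edge-stability (Jaccard), a mixing-coefficient grid
    search, and a synthetic cohort generator with planted subtype structure
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    igraph,
    glmnet,
    data.table,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
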