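Package: ngsqc
Title: Machine-Learning Quality Control for NGS Data Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives four quality feature sets from next-generation sequencing
    data -- FastQC-style read-level flags (RAW), aligner mapping statistics
    (MAP), read fractions over nine genomic region categories (LOC), and binned
    read density around transcription start sites (TSS) -- and trains
    probability-calibrated classifiers that score the probability that a
    sequencing file is of low quality. Includes one-feature ROC baselines,
    grid-search model tuning with feature selection and stratified
    cross-validation, leave-experiment-out and cross-species evaluation
    protocols, Cistrome-style quality-flag validation, PCA/Dunn-index outlier
    screening for expression studies, and seeded synthetic-data generators
    (genomes, FASTQ, alignments, labeled feature tables) so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ranger,
    rpart,
    e1071,
    nnet,
    class,
    xgboost,
    glmnet,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    Rsamtools
Config/testthat/edition: 3
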