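Package: episig
Title: DNA Methylation Episignature Discovery, Validation and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A case-control pipeline for blood DNA methylation episignatures
    on EPIC-style beta-value matrices: probe quality filtering, control
    matching, logit (M-value) transformation, per-probe linear modelling with
    cell-composition covariates and empirical-Bayes variance moderation,
    multi-stage probe selection (effect-significance product, ROC AUC,
    correlation pruning), leave-one-out cross-validation, a linear SVM
    classifier emitting 0-1 methylation variant pathogenicity (MVP) scores
    for variant reclassification, cross-cohort DMP overlap and clustering,
    CpG-island and gene-context enrichment, DMR calling, and a synthetic
    cohort generator with planted episignatures so the whole pipeline runs
    and is testable without array downloads. Includes parsing and
    summarisation of an HGVS-style variant cohort table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
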