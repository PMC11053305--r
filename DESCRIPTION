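Package: fragscreen
Title: Genome-Wide cfDNA Fragmentation Profiling for Liver Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for circulating cell-free DNA (ccfDNA) fragmentomics in
    cancer screening. Builds ~5-Mb genomic analysis windows from 100-kb bins
    on non-acrocentric autosome arms, converts aligned cfDNA fragments into
    per-bin short-fragment (100-167 nt) proportion profiles, trains an
    L1-penalized logistic detection model with repeated stratified
    cross-validation, evaluates screening performance by time-to-diagnosis
    window (exact binomial confidence intervals, ROC/AUC with DeLong
    intervals, incidence-based positive and negative predictive values), and
    relates the fragmentation score to patient survival (Kaplan-Meier,
    log-rank, Cox proportional hazards). A synthetic fragment-cohort
    generator with a nucleosome-peaked size distribution, tumour-fraction
    growth model and linked survival outcomes makes every stage testable
    without access to patient data.
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
    GenomeInfoDb,
    SummarizedExperiment,
    Rsamtools,
    glmnet,
    survival,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
biocViews: Sequencing, Classification, Survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
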