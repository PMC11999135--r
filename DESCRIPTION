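Package: promfoot
Title: Promoter Nucleosome-Footprint Profiling of Plasma Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling plasma cell-free DNA (cfDNA) read coverage
    over promoter windows around transcription start sites (pTSS), where
    nucleosome protection leaves a sequencing footprint anticorrelated with
    gene expression in the tissues of origin. The package builds
    strand-oriented 2-kb pTSS windows from gene annotation, counts cfDNA
    fragments and normalizes coverage, tests for differential promoter
    coverage between clinical groups (Wilcoxon rank-sum with
    Benjamini-Hochberg FDR), discretizes coverage at AUC-optimal cutoffs,
    ranks and prunes features (SVM-RFE, correlation pruning), and builds
    classifiers (SVM, logistic regression, random forest, XGBoost) with
    backward or lasso feature selection, cross-validated and leave-one-out
    AUC evaluation, and DeLong confidence intervals and paired AUC tests.
    A synthetic cohort generator with planted differential-coverage effects,
    a nucleosome-depleted region model, and fragment-level sampling supports
    calibration and recovery testing of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    e1071,
    glmnet,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
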