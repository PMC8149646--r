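Package: coprofile
Title: Single-Cell mRNA and Intracellular Protein Co-Profiling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for single-cell experiments that co-profile
    global mRNA (full-length scRNA-seq with ERCC spike-ins) and multiplexed
    intracellular proteins (proximity extension assays read out as qPCR Cq
    values) from the same cells. Provides plate-level PEA processing (well
    quality control, extension-control normalization, buffer-background
    correction, detectability filtering), scRNA-seq cell QC and RPM/RPKM
    normalization, cell-cycle module scoring and covariate regression,
    principal-trajectory pseudotime with cross-modality ordering
    concordance, transcription-factor target inference from tree-ensemble
    link weights with ROC/AUC and permutation evaluation, and decomposition
    of expression variation (CV2 mean-dependence residuals, translation-rate
    estimates, and an additive predictor of protein variability). A
    stochastic simulator of coupled bursty transcription and translation,
    with both measurement layers, supplies ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    splines
Suggests:
    testthat (>= 3.0.0),
    Rtsne,
    pROC,
    jsonlite
Config/testthat/edition: 3
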