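Package: ccfRisk
Title: Cancer Cell Fraction Based Recurrence Risk Modelling from Targeted
    Tumor Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers per-mutation cancer cell fractions (CCF) and clonality
    from targeted deep-sequencing allele counts, copy number and tumor
    purity; assembles gene-level CCF matrices; screens alterations for
    survival association and classifies CCF-dependent prognostic patterns;
    fits SCAD-penalized Cox models with cross-validation, stepwise BIC
    filtering and stability selection; stratifies patients by recursive
    partitioning of the risk score; and evaluates predictors with IPCW
    time-dependent ROC analysis. Ships a synthetic tumor-cohort simulator
    with known ground truth for end-to-end recovery testing, and a packaged
    published eight-gene esophageal squamous cell carcinoma recurrence
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    mclust,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Survival, SomaticMutation, Sequencing, Classification
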