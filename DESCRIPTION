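Package: MetaboPanel
Title: Plasma Metabonomic Biomarker Panel Discovery and Ensemble Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for GC/MS plasma metabonomics biomarker-panel discovery.
    Implements internal-standard (relative peak area) normalization, PCA and
    PLS-DA profiling with VIP-based differential-metabolite selection, nested
    logistic-regression panels scored by ROC AUC, and a forward-selection
    classification system ("Tclass") built on Fisher linear discriminant and
    Gaussian naive Bayes base learners: greedy feature selection under
    leave-one-out cross-validation, a resampling stability index over 1000
    random 85/15 train/test splits, 1000-classifier majority-vote ensembles,
    and a hierarchical disease-subtype prediction tool. Ships a reference
    catalog of 35 plasma metabolites with per-group moments and VIP
    annotations, a printed example classifier pair, and a synthetic cohort
    generator so the full pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    knitr
Config/testthat/edition: 3
biocViews: Metabolomics, Classification, BiomedicalInformatics
RoxygenNote: 7.3.3
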