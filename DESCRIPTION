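Package: prognet
Title: Network-Based Prognostic Biomarker Selection and Bimodal Deep
    Learning for Lung Cancer Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prognostic stratification of non-small cell lung
    cancer from gene expression and clinical data. Implements StepMiner
    step-function dichotomization of biomarker expression, paired
    biomarker+/- co-expression interaction networks restricted to a
    reference interactome, per-gene prognosis relevance values (PRV) with
    list-overlap and log-rank survival filtering for biomarker panel
    selection, feed-forward neural classifiers for expression and clinical
    features merged into a jointly fine-tuned bimodal network, benchmark
    classifiers (k-nearest neighbours, random forest, support vector
    machine) with cross-validated hyper-parameter search, ROC/AUC
    evaluation with Youden-index reclassification, and Kaplan-Meier,
    log-rank and Cox proportional-hazards analysis of predicted risk
    groups. A synthetic cohort generator with planted network and survival
    effects makes the whole pipeline reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    class,
    ranger,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
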