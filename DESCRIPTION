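Package: radbench
Title: Benchmarking Machine-Learning Methods for Radiomic Survival Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evaluation framework for machine-learning pipelines built on
    tabular radiomic features with right-censored survival outcomes. Provides
    cohort preparation (survival dichotomization with short-follow-up
    exclusion, Z-score normalization), fourteen filter feature-selection
    methods (Fisher score, Relief, t-score, chi-square, Wilcoxon, Gini index,
    and the greedy information-theoretic family MIM/MIFS/MRMR/CIFE/JMI/CMIM/
    ICAP/DISR), a twelve-family classifier harness with repeated stratified
    cross-validation, feature-selection stability via maximum-weight bipartite
    matching with absolute Spearman correlation weights, classifier stability
    via the relative standard deviation of bootstrap AUCs, median-based method
    ranking with quadrant (reliable-and-accurate) classification, multifactor
    ANOVA variance decomposition of AUC grids, and a synthetic two-cohort
    generator with planted prognostic features for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    glmnet,
    mixOmics,
    nnet,
    randomForest,
    rpart,
    xgboost,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
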