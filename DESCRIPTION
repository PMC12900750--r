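Package: mddpanel
Title: Peripheral Transcriptomic Biomarker Discovery for Adolescent Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for peripheral-blood biomarker
    discovery in adolescent major depressive disorder: negative-binomial
    exact-test differential expression screening, hub-gene identification by
    subgraph centrality intersected with MCODE network modules,
    covariate-adjusted clinical correlation statistics (partial Spearman,
    Shapiro-Wilk-gated group tests, 2^-ddCt fold changes), and a
    tri-algorithm machine-learning feature-selection consensus (LASSO
    stability selection, SVM-RFE with leave-one-out cross-validation,
    random-forest Gini importance) with ROC and permutation validation.
    Includes a seeded synthetic-cohort generator emulating the statistical
    structure of a 15-vs-15 case-control PBMC RNA-seq study so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    glmnet,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
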