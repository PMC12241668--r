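Package: lactoscore
Title: Consensus Lactylation Activity Scoring and State Discovery in
    Single-Cell and Bulk Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores every cell of a single-cell (or spot of a spatial)
    expression matrix against a lactylation-related gene signature with five
    independent rank- and expression-based algorithms (AUC recovery curve,
    rank-U, mean-rank, weighted running-sum enrichment, and bin-matched
    module score), fuses the min-max normalized scores into a 0-1 consensus,
    and stratifies cells into low / dynamic-transition / high lactylation
    states by the interquartile-range rule. Downstream stages find
    state-associated genes by Wilcoxon differential expression, a
    WGCNA-style co-expression module core (metacell aggregation,
    soft-threshold adjacency, topological overlap, eigengenes, kME hubs),
    and a five-algorithm machine-learning intersection (LASSO, univariate
    Cox, random forest, Boruta shadow features, gradient boosting). A
    negative-binomial simulator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    mclust,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
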