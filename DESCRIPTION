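Package: chlmda
Title: Combinative Hypergraph Learning for miRNA-Disease Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts miRNA-disease associations by fusing multiple similarity
    sources (DAG-based disease semantic similarity, miRNA functional similarity,
    and Gaussian interaction-profile kernels computed from a weighted
    K-nearest-neighbour-completed association matrix), engineering statistical
    and graph-theoretic features for each miRNA-disease pair, building KNN and
    K-means hypergraphs over the pair features, and learning a closed-form
    Laplacian-regularised projection per hypergraph together with simplex
    combination weights. Includes leave-one-out and k-fold cross-validation
    drivers with strict per-fold similarity recomputation, a rank-based AUC,
    a feature-family ablation driver, and a synthetic low-rank data generator
    so the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
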