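Package: netprio
Title: Target Prioritization on Heterogeneous Multi-Layer Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds heterogeneous multi-layer biological networks (gene,
    protein, metabolite, Gene Ontology and pathway layers with mixed
    directed and undirected edges), extracts eleven categories of
    per-protein features (random-walk-with-restart and shortest-path
    propagation under three directionality modes, topological metrics and
    inverse-log-weighted similarity, proximity to detected modules and
    cliques, and proximity to disease gene signatures), selects features
    with a bootstrap cascade (information gain against a rewired-network
    null, correlation pruning, repeated adaptive LASSO and random-forest
    importance), trains imbalance-aware classifiers scored by the Matthews
    correlation coefficient, and calls candidate therapeutic targets with
    a positive-unlabeled cross-validation voting ensemble.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    glmnet,
    randomForest,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
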