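Package: netclosure
Title: Directed Closure Coefficients and Triangle-Formation Metrics for Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures triangle formation in directed networks from the
    end-node perspective. Implements the directed closure coefficient and
    its source/target variants, the four transitive closure patterns
    (head-of-path, mid-of-path, end-of-path, cyclic), directed clustering
    coefficients and their patterns, and weighted and signed extensions
    for trust-style networks. Also provides closure-based link-prediction
    indices (CCI, ECCI) with a precision-recall evaluation protocol,
    network-level signature features with a tree-based classification
    harness, exact brute-force triad/triangle oracles for verification,
    seeded synthetic graph generators, and a command-line interface for
    plain-text edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    rpart,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
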