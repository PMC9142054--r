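Package: kefrin
Title: Community Detection in Feature-Rich Networks by Extended K-Means
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions the nodes of a feature-rich (node-attributed) network
    by alternating minimization of a combined least-squares criterion over the
    feature space and the network-link space, in three metric variants (squared
    Euclidean, Manhattan, cosine). Includes the data-standardization operators
    used by the method (z-scoring, range scaling, modularity shift, scale
    shift), a planted-partition synthetic benchmark generator with quantitative,
    categorical and mixed node features, Adjusted Rand Index and Normalized
    Mutual Information evaluation, and a benchmark harness over grids of
    generator settings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
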