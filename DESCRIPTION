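Package: clagr
Title: CLAG Deterministic Quantile-Grid Clustering and Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unsupervised, non-hierarchical, deterministic clustering of
    M x N biological data matrices (expression profiles, coevolution or
    correlation score matrices) with the CLAG algorithm. Entry
    distributions are discretized into shifted delta-quantile grids that
    define closeness between entries; environmental and symmetric scores
    for element pairs drive a generator-based clustering step, and a
    cluster-aggregation step merges ranked affine clusters into a colored
    aggregation graph whose monochromatic components ("key aggregates")
    are the disjoint output clusters. Includes a Gaussian-cluster
    benchmark generator with recovery scoring and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
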