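Package: dynhub
Title: Dynamic Betweenness-Centrality Modes of Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-varying hub topology of region-level
    functional brain networks. Segments BOLD-like time series into sliding
    windows, computes windowed Fisher-z Pearson connectivity, binarizes each
    window by a proportional threshold, derives rank-based betweenness
    centrality per node and window, clusters each node's rank trace into
    "centrality modes" with cityblock k-means selected by a composite
    cluster-validity criterion, and tests the association between
    high-centrality-mode occupancy and an ordinal impairment score with a
    permutation test. Includes a synthetic-cohort generator with a planted
    state-switching hub so that every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    cluster,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
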