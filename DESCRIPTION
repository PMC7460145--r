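Package: pmcompare
Title: Pairwise Comparison of Care-Process Models from Clinical Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing care processes of patient populations mined
    from clinical event logs. Reads and writes event logs (XES and CSV), splits
    logs into attribute-defined patient populations and measures their overlap,
    discovers process models with an inductive-miner-family algorithm
    (frequency-annotated operator trees and workflow Petri nets), converts both
    model representations into typed directed graphs, and compares model pairs
    with a type-aware graph edit distance, a feature-vector graph similarity,
    and cross-log conformance checking (token-replay fitness and escaping-edges
    precision). Includes a synthetic clinical event-log generator with
    controlled population overlap and deviation injection, and Spearman
    rank-correlation analysis for validating similarity measures against human
    visual-similarity ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    tibble,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
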