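Package: netRepeat
Title: Repeatability of Community Detection and Hub Identification in
    Weighted Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing the test-retest repeatability of community
    detection and hub identification in weighted structural brain networks.
    Implements orthogonal-minimal-spanning-tree (OMST) topological filtering,
    data-driven integration of multiple edge-weight metrics, seven
    graph-construction schemes, fast multi-scale community detection under
    several quality criteria, link-community soft covers, normalised mutual
    information partition similarity with bootstrap significance, degree- and
    strength-preserving surrogate null models, consensus clustering,
    participation-coefficient / within-module z-score hub cartography with a
    cross-cohort agreement index, ICC-based reliability statistics, and a
    pipeline that ranks scheme-algorithm pairs by repeatability. Includes a
    synthetic test-retest cohort generator with planted modular ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
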