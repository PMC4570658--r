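Package: devodup
Title: Developmental Expression Biclustering and Gene Duplication Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of developmentally regulated gene clusters from a
    ternary pairwise differential-expression matrix via sign-consistent
    biclustering, classification of a proteome into five orthology classes
    with an inparalog-aware reciprocal-best-hit procedure and paralog-graph
    connected components, and enrichment and correlation analyses linking
    stage-specific expression to lineage-specific gene duplication. Includes
    a synthetic-data module that generates two-species gene families,
    similarity hits and stage-structured expression with known ground truth
    so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    ape,
    phytools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
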