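Package: orthotri
Title: Hierarchical Ortholog Delineation by Best-Reciprocal-Hit Triangulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates hierarchical orthologous groups across sets of
    proteomes using all-vs-all Smith-Waterman local alignment, best
    reciprocal hit (BRH) detection, in-paralog identification and
    triangulation clustering at taxonomy-defined orthology levels.
    Computes per-group evolutionary annotations (phyletic profiles,
    normalized evolutionary rates, gene architecture statistics, sibling
    groups), benchmarks predicted clusterings against reference groups
    with precision/recall/F1, a six-way event classification and the
    Variation of Information metric, and ships a birth-death gene-family
    simulator that produces synthetic proteomes with known ortholog
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
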