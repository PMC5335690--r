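Package: synthtree
Title: Ranked Supertree Synthesis from Phylogenies and a Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Merges a comprehensive rooted taxonomy with a ranked collection
    of rooted phylogenetic trees into a single summary supertree with no
    unsupported edges and no unnecessary polytomies. Implements a rooted-split
    calculus (display, conflict, support), taxonomy flag-cleaning and id
    forwarding, input-tree cleaning and higher-taxon exemplification,
    decomposition into subproblems at uncontested taxa, greedy rank-ordered
    split incorporation checked with a BUILD algorithm generalized to rooted
    splits, solution grafting, unpruning of taxonomy-only taxa, stable node
    naming, and a node-provenance annotation document recording which input
    edges support, conflict with, or are resolved by each summary edge.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
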