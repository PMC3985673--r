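Package: modmapr
Title: Module Maps from Paired Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Constructs module maps from two networks defined on a shared
    gene set: disjoint modules that are densely connected in a first
    network (for example protein-protein interactions or consistent
    co-expression) joined by statistically significant inter-module links
    in a second network (for example genetic interactions or differential
    co-expression). Provides maximal-biclique and clustering-based
    initiators, local and global improvement of a map-wide score with
    hypergeometric/Fisher and Wilcoxon/Stouffer link tests, anti-link
    caching and batched merges, a planted-map simulator with decoy
    structures and flip or Gaussian noise, recovery evaluation against
    planted truth, classification of treatment-specific genetic
    interactions, and import/export of edge lists and Cytoscape-compatible
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
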