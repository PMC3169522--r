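Package: glidevol
Title: Comparative Genomics of the Emergence of a Bacterial Gliding Motility Machinery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale comparative-genomics pipeline for tracing the
    origin of the Myxococcus xanthus Agl/Glt gliding motility machinery:
    feature-based candidate screening of mutant-screen gene lists,
    chromosomal cluster detection by locus-tag adjacency, iterative
    homologue search with phyletic profiling and taxonomic-breadth
    classification, synteny-resolved supermatrix construction,
    distance-based tree inference with nonparametric bootstrap, and
    reconstruction of gain/loss/duplication/transfer evolutionary
    scenarios.  Includes a gene-family birth-death-transfer simulator with
    sequence evolution, synteny-aware genome assembly and ground-truth
    event logs, so every inference step can be scored against a known
    history.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
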