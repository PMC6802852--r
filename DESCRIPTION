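Package: scbav
Title: Single-Cell Bifurcation Analysis Using Variance of Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs cell-lineage trees from time-stamped single-cell
    RNA-seq expression data, detects cell-fate bifurcations, and screens for
    putative upstream regulators of each bifurcation by combining
    pre-bifurcation expression variability with consistent post-bifurcation
    differential expression between branches. Also provides marker-based
    lineage assignment with expression-bin-matched control genes, a
    maintained-marker filter, hypergeometric marker-set enrichment, and a
    seeded negative-binomial simulator of bifurcating time-series count data
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
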