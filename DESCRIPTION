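Package: coexmod
Title: Automated Gene Co-Expression Module Discovery and Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for weighted gene co-expression network
    analysis from a single gene-by-sample expression matrix. Genes are
    selected by modelling per-gene variances with an inverse-gamma
    distribution (with an optional negative-binomial variance-stabilizing
    transformation for count data), a soft-thresholding power is chosen
    automatically by a Cauchy-sequence stabilization criterion on the
    scale-free topology fit curve, co-expression modules are detected by
    hierarchical clustering of the topological overlap matrix with an
    adaptive tree cut, and modules are characterized by hypergeometric
    over-representation analysis, permutation-based gene set enrichment
    analysis across phenotype classes, and interactome-based hub discovery.
    Results are emitted as machine-readable tables and a static HTML report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
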