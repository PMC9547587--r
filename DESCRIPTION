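Package: mirtrait
Title: Inferring and Analysing miRNA-Disease Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives bidirectional miRNA-disease association databases by
    merging curated miRNA-to-target-gene and gene-to-disease mapping tables on
    the shared gene key, and provides an analytical toolkit for the result:
    disease and miRNA spectrum widths, one-sided hypergeometric (Fisher exact)
    disease-enrichment analysis of miRNA lists with Bonferroni, Holm or
    Benjamini-Hochberg correction, diseasome miRNA-abundance profiling,
    pairwise overlap-enrichment networks, and consensus ranking of hub nodes
    across seven weighted centrality measures plus Monte-Carlo edge-percolation
    centrality. Includes a synthetic-fixture generator with plantable hubs,
    enriched diseases and cliques, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
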