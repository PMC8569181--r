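Package: dndphage
Title: DNA Phosphorothioation Systems, Prophage Co-Occurrence and Fitness Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the ecology of DNA phosphorothioate (PT)
    modification systems in prokaryotes. Detects dnd genes and gene clusters
    (dndCD, dndBCDE, dndFGH) from homology-hit tables using adjacency and
    restriction-modification linkage rules, assigns viral-family taxonomy to
    prophage regions by a majority rule, and quantifies the association
    between dnd systems and prophage occurrence across and within taxa
    (ordinary least squares/Pearson across taxa, tie-corrected Kendall tau-b
    within taxa). Includes PT consensus-motif (GAAC/GTTC) scanning,
    modification-frequency arithmetic, site-to-gene mapping, coupling of PT
    sites with differential expression, relative-fitness estimation from
    serial-transfer competition assays, and seeded synthetic-data generators
    that make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
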