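Package: bgcfam
Title: Comparative Analysis of Biosynthetic Gene Cluster Families in
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative genome mining of secondary-metabolite
    biosynthetic gene clusters (BGCs) in bacterial genera such as the
    actinomycetes. Calls gene clusters from signature-enzyme hits with a
    six-gene window-extension rule, tallies cluster classes per genome
    (counting hybrid clusters once per class), computes pairwise genome
    similarity from ortholog groups with a min-copy counting rule, groups
    clusters into gene cluster families by homolog-content similarity,
    builds per-genus conservation histograms, delineates cluster
    boundaries from the drop in conserved gene content, screens proteins
    for the phosphonate-biosynthesis PepM motif, selects single-copy
    ribosomal-protein ortholog groups for concatenated phylogenies, and
    summarises candidate lanthipeptide precursor peptides as
    position-frequency matrices. A bundled synthetic-genus simulator with
    a truth manifest makes every stage testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    Biostrings,
    ape,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
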