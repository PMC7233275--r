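Package: hrmhap
Title: High-Resolution Melt Haplotype Screening and Chloroplast Phylogeography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for genotyping chloroplast haplotypes with
    high-resolution melt (HRM) analysis and analysing the resulting
    population data. Ingests qPCR plate runs (amplification and melt
    curves), screens amplification quality, normalises melt curves and
    calls melt peaks, clusters curves into putative haplotypes using a
    delta-Tm threshold plus curve-shape similarity, scores haplotype
    discrimination (sensitivity, specificity, accuracy) against known
    identities, assigns verified haplotypes to duplicate-run field
    samples, and carries the haplotype tables through a chloroplast
    phylogeography workflow: pairwise Gst, G''st, Jost's D and Prevosti
    differentiation, Mantel isolation-by-distance tests, hierarchical
    AMOVA, statistical-parsimony haplotype networks and neighbour-joining
    population clustering. A seeded simulator generates melt curves from
    haplotype sequence differences (SNP-class-dependent melt-temperature
    shifts plus noise) so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
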