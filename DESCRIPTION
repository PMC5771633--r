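Package: fescuephylo
Title: Chloroplast Variant Calling, Diagnostic Markers and Clade Dating for
    Tall Fescue Morphotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for molecular discrimination of tall fescue (Festuca
    arundinacea) morphotypes and related Festuca species from chloroplast
    sequence variation and SSR fragment data. Calls and classifies SNP,
    single-base deletion and multi-base indel polymorphisms from gapped
    multiple alignments; computes a between-group similarity index;
    discovers morphotype-diagnostic indel markers and predicts their PCR
    product sizes in silico; scores SSR primers for group-discriminating
    fragments; builds UPGMA trees from Nei-Li/Dice similarities on binary
    marker matrices and from Tamura-Nei (TN93) sequence distances, with
    column-resampling bootstrap support; constructs median-joining
    haplotype networks and dates clades with the rho statistic scaled by a
    per-mutation rate. A synthetic-data module plants group-structured
    variants with truth tables so every stage is testable end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
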