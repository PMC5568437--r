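Package: spidromotif
Title: Motif-Based Analysis of Spider Silk Protein Tandem Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the motif-based analysis of major ampullate spidroin
    (MaSp) repetitive domains. Detects poly-alanine runs, segments spidroin
    repetitive regions into tandem repeat units, scans repeats for an explicit
    catalog of short glycine-led motifs (GX, GGX) and doublets (QQ, SS) under
    precedence rules, derives conserved and consensus motif profiles,
    classifies sequences as MaSp1 or MaSp2, matches the extended Araneidae
    MaSp2 consensus around each poly-alanine run, and quantifies motif
    abundance against repeat length and spider web architecture. Includes a
    seeded generator of synthetic spidroin-like sequences with planted motif
    composition for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
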