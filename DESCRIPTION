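Package: fatac
Title: Chromatin Accessibility and Transcription-Factor Footprinting for Fungal ATAC-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing ATAC-seq data from compact fungal genomes:
    conversion of aligned paired-end fragments into strand-resolved Tn5
    insertion tracks, library quality diagnostics (fragment-length
    periodicity, TSS enrichment, replicate correlation), accessible-region
    calling with a local-Poisson sliding-window scan, count-based
    differential accessibility, Wellington-style strand-aware footprint
    detection inside peaks, IUPAC consensus motif scanning and enrichment,
    and a strand-asymmetry permutation test that separates protein-bound
    footprints from Tn5 sequence-preference artefacts. A seeded synthetic
    data generator emulates the statistical structure of fungal ATAC-seq
    libraries (nucleosomal fragment-length ladder, promoter nucleosome-free
    regions, planted footprints with oriented strand bias) so every stage is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse
Config/testthat/edition: 3
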