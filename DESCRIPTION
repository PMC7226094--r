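Package: wellscreen
Title: Single-Clone Phage Microwell Screening: Simulation, Imaging and Clone Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing single-clone phage display
    screens run on microwell array chips. Provides closed-form Poisson
    single-cell loading statistics, degenerate-codon library complexity
    calculations, a synthetic-data generator (chip images, pooled sequencing
    reads, ELISA plates) with known ground truth, tile stitching and per-well
    fluorescence quantification, fiducial-based affine registration between
    pre- and post-disassembly coordinate frames with retrieval planning, an
    scFv clone-identification and mutation-filtering funnel, and
    ELISA-threshold hit confirmation, orchestrated end to end by a single
    pipeline entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
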