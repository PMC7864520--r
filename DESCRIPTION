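Package: saaquant
Title: Quantification of Seeded Serum Amyloid A Aggregation from Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify seeded aggregation of serum amyloid A (SAA)
    protein from fluorescence micrographs using the per-pixel brightness
    standard-deviation statistic, with replicate time-course summaries,
    Boltzmann sigmoid kinetics fits, half-maximal (EC50-style) dose-response
    fits on the amyloid-enhancing-factor (AEF) axis, z-stack thickness
    profiling, and dotted-versus-mesh morphology classification. A companion
    sequence-homology toolkit performs affine-gap global alignment,
    progressive multiple sequence alignment, percent-identity and
    conservation-class summaries, UPGMA tree building, and a physicochemical
    discriminative-site scan relating species-level seeding activity to SAA
    sequence features. A synthetic-data module simulates seeded
    nucleation-elongation kinetics, renders micrographs and z-stacks in two
    morphologies, and generates SAA-like sequence families with planted
    discriminative sites, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    deSolve,
    minpack.lm,
    ape,
    Biostrings,
    EBImage,
    tiff,
    png,
    yaml,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
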