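Package: immunofishr
Title: Quantitative Analysis of Combined Single-Molecule RNA FISH and
    Immunofluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for quantitative analysis of multi-channel 3D
    fluorescence microscopy experiments that combine single-molecule RNA
    FISH with immunofluorescence (immunoFISH). Provides 3D
    Laplacian-of-Gaussian spot detection with automatic thresholding,
    nucleus/micronucleus/cell segmentation, compartment assignment and
    intron-exon colocalization for pre-mRNA classification,
    transcription-focus detection, per-nucleus control-point warp
    registration across staining rounds, per-cell transcript and protein
    quantification, and a ground-truthed synthetic image generator so the
    entire pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
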