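Package: ctfish
Title: Quantification of Chromosome Territories in 3D FISH Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying chromosome territories
    (CTs) in multi-channel 3D fluorescence in situ hybridization (FISH)
    image stacks, as produced by Oligopaint chromosome painting of
    Drosophila interphase nuclei. Segments the nucleus from a DNA
    counterstain and per-channel territories by 3D hysteresis thresholding
    or Laplacian-of-Gaussian spot detection, then computes per-cell volume
    fractions, pairwise voxel-overlap and contact frequencies, homolog
    pairing state, equal-volume radial shell profiles, mesh-based
    sphericity (compacity), minimal edge-to-edge probe distances, and
    open/closed three-probe fold configurations. Population summaries
    reproduce heatmap, box-summary, correlation and rank/Fisher test
    readouts, and flag candidate translocations from elevated overlap. A
    bead-chain nucleus simulator with a tunable confinement (compaction)
    dial, homolog pairing, translocations and sub-arm band probes renders
    ground-truthed synthetic microscopy (PSF blur, Poisson shot noise,
    Gaussian read noise) for validating every measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    xml2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    igraph
Config/testthat/edition: 3
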