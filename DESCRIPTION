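Package: qpitrack
Title: Quantitative Phase Imaging Analysis of Cell Growth, Motility and
    Invasion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for label-free quantitative phase imaging (QPI) of
    living cells with an incoherent-source phase-shifting interference
    microscope, and for two-channel fluorescence invasion assays.
    Reconstructs optical path difference from four phase-shifted
    interferograms, removes frame-to-frame background fluctuations,
    reconstructs and subtracts the cell-free background from the temporal
    mode of each pixel, converts optical path to dry-mass surface density,
    segments and tracks cells, and derives growth (dry-mass doubling
    time), centroid speed, protrusion/retraction and dynamic polarity.
    Includes circular statistics for chemotaxis (horizon-crossing
    directions, Rayleigh test, hierarchical unbalanced ANOVA on gradient
    displacement components), contingency-table chi-square tests, invasion
    scoring against monolayer openings, and a seeded synthetic-scene
    generator so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Matrix,
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
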