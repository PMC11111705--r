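Package: arborseg
Title: Topology-Informed Segmentation, Parcellation and Morphometry of 3-D
    Neuron Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step reconstruction of neurons from 3-D fluorescence
    microscopy stacks. Step one segments neuronal structure by K-means
    clustering in a four-dimensional feature space (image intensity plus
    the second spatial derivatives along x, y and z), with automatic
    selection of the number of classes and multi-scale merging across
    Gaussian smoothing levels. Step two separates touching neurons and
    assigns detached dendritic spines to their parent dendrite with a
    marker-controlled 3-D watershed on the morphologically reconstructed
    intensity complement. The package also skeletonizes single-neuron
    masks to SWC trees and computes Horton-Strahler, Sholl, Dice, surface
    area/volume and spine detection statistics, and ships a seeded
    synthetic phantom generator with exact ground truth so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
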