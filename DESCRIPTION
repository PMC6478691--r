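Package: pulmolymph
Title: Morphometry and Coupled Stokes-Darcy Microfluidics of Pulmonary
    Lymphatics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reproduction pipeline for three-dimensional
    morphometry of human pulmonary lymphatic networks and steady
    microfluidic modelling of peripheral lung tissue.  Provides a
    synthetic labelled-volume generator emulating segmented micro-CT
    lung geometry (pleural slab, blood-vessel tree, depth-graded and
    partially collapsed lymphatic network, alveolar airspaces), the six
    lymphatic morphometric measures (volume fraction, surface area per
    tissue volume, box-counting fractal dimension, branch and junction
    counts, tortuosity), region-of-interest sampling and subpleural
    classification by Euclidean distance mapping, image preparation for
    modelling (upsampling, median filtering, connectivity pruning,
    class precedence), a voxel finite-volume solver for coupled Stokes
    (vessel lumen) and Darcy (interstitium) flow joined by a
    membrane-conductivity flux condition with backflow suppression, and
    the accompanying statistics (exact Mann-Whitney U, distance
    regression, parameter sensitivity protocol).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
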