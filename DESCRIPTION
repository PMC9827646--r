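Package: cellwallfem
Title: Cell Wall Finite Element Models from Plant Tissue Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automated digitization of stained plant-stem cross-section
    micrographs into two-dimensional cell-wall beam finite element models.
    Provides the full chain: brightfield image preprocessing (8-bit
    conversion, sharpening, contrast windowing, despeckling), cell-wall
    segmentation by band thresholding or a trainable pixel classifier,
    exact Euclidean distance maps and wall thinning, Voronoi tessellation
    of cell interiors with wall-graph extraction and spur pruning, cell
    morphometrics (counts, areas, size histograms, rank-colored renderings),
    a 2D Timoshenko beam-network solver for tissue structural stiffness and
    cell-wall von Mises stress with Abaqus INP export, and forward-difference
    normalized sensitivity analysis of wall thickness and wall modulus.
    Includes a parametric honeycomb fixture generator with ground-truth
    labels and the Gibson-Ashby closed-form honeycomb modulus as an
    independent oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    png,
    tiff,
    randomForest,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
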