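Package: embryoforce
Title: 3D Morphological Reconstruction and Force Inference from Membrane Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs cell-scale geometry from 3D membrane probability
    volumes and infers the mechanical state of early embryos. A seeded watershed
    turns a probability map into labelled cells, one-voxel-thick membrane faces
    and their face/junction topology; membrane faces are smoothed into oriented
    point clouds by local principal component analysis, per-point mean curvature
    is estimated from quadric fits via the Weingarten map, and triple junctions
    are thinned into curves carrying the three dihedral angles between membranes.
    Membrane tensions and cell pressures are then inferred by solving the
    overdetermined linear system formed by Young-Laplace relations, junction
    tension balances and two gauge rows, with residual reports, a sensitivity
    spectrum of the pseudoinverse, and per-cell stress and shape tensors. An
    analytic two-cell generator provides ground-truth fixtures for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    purrr,
    withr
Config/testthat/edition: 3
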