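Package: tfocm
Title: Traction Force Optical Coherence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs time-resolved three-dimensional cellular traction
    forces from spectral-domain optical coherence microscopy (OCM) time-lapse
    data of cells embedded in bead-seeded elastic hydrogels. Implements the
    full computational chain: a six-step computational image formation module
    (volume reconstruction, coherence-gate curvature removal, focal plane
    registration, phase registration, bulk demodulation, and computational
    adaptive optics refocusing), bead localization and feature-vector tracking
    with rigid-drift correction, speckle-reduced cell segmentation and
    meshing, a linear-elastic finite-element forward solver with an analytic
    Kelvin-solution oracle, and a Tikhonov-regularized inverse solver with
    exact force and moment balance and L-curve regularization selection. A
    synthetic-data module emulates the microscope (defocus, coherence-gate
    curvature, phase jitter, bulk carrier, sensor noise) and pushes known
    traction fields through the forward solver so that every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
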