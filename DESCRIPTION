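Package: rootgpr
Title: Synthetic Ground-Penetrating Radar Imaging of Tree Roots in Layered Heterogeneous Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for training and evaluating deep
    inversion models that map ground-penetrating radar (GPR) B-scans to
    subsurface permittivity maps of tree roots buried in layered
    heterogeneous soil. Includes a Peplinski soil dielectric mixing model
    with ISSS texture classification, a randomized layered-scene generator
    with root-like scatterers, a 2-D finite-difference time-domain (FDTD)
    electromagnetic solver with perfectly matched layer boundaries, the
    B-scan preprocessing chain (background removal, time gain,
    normalization, label construction), a dual-branch pyramidal-convolution
    / vision-transformer inversion network with an edge-inversion auxiliary
    task, and a training, evaluation and transfer-learning harness built on
    a compact reverse-mode neural-network engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tibble,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
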