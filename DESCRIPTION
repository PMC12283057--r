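Package: dualswift
Title: Simulation and Analysis of Dual Field-of-View Zero-TE MB-SWIFT fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Desk-scale simulator and analysis pipeline for simultaneous
    dual field-of-view (brain and spinal cord) zero echo time MB-SWIFT
    functional MRI. Generates interleaved 3D-radial spoke schedules,
    dual-organ digital phantoms with block-design hemodynamic responses,
    forward-models the radial k-space acquisition, reconstructs image
    series by RF-pulse deconvolution, spoke apodization,
    density-compensated gridding and FISTA, and implements the functional
    statistics chain: centre-of-mass motion estimation and correction,
    ICA-based motion-component regression, high-pass filtering, AR(1)
    prewhitening, a voxelwise GLM with a gamma-variate impulse response,
    cluster extraction, threshold-free cluster enhancement and sign-flip
    permutation inference with family-wise error control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
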