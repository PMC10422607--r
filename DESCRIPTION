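Package: pabreast
Title: Simulation and Deep-Learning Artifact Removal for 3D Photoacoustic
    Breast Imaging with Hemispherical Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end simulation and reconstruction pipeline for
    three-dimensional photoacoustic tomography of the breast with a
    hemispherical transducer array. Generates procedural digital breast
    phantoms with seven tissue classes, runs voxel Monte-Carlo photon
    transport at 757 nm to obtain the absorbed optical energy and initial
    pressure, projects the initial pressure to band-limited per-element
    channel data with the exact homogeneous-medium forward model, forms
    images by 3D delay-and-sum, and removes sparse-sampling artifacts with
    a 3D residual U-Net trained on a composite L1 + multi-scale structural
    similarity loss. Includes 3D PSNR and MS-SSIM metrics and a sparsity
    sweep evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
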