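Package: funCI
Title: Functional Conductivity Imaging from MRI Transceive Phase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs quantitative tissue electrical-conductivity maps
    from MRI transceive phase using a tissue-restricted average-parabolic-fit
    Laplacian (phase-based MR electrical properties tomography), and detects
    stimulus-locked conductivity changes in dynamic acquisitions through
    jitter-pooled response-function estimation with a discrete Laguerre basis
    and voxelwise general linear model activation mapping. Includes
    region-growing 3D phase unwrapping, adaptive nonlinear phase denoising,
    and a synthetic phantom simulator whose forward model is analytically
    consistent with the reconstruction, so the whole pipeline is testable
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
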