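Package: geldose
Title: Polymer Gel Dosimetry Analysis with Multi-Echo MRI and 3D Gamma Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of polymer-gel dosimetry experiments read out by
    multi-echo magnetic resonance imaging. Provides a synthetic phantom and scanner
    simulator (breast-shaped gel phantom with a tissue-expander metal port, analytic
    two-tangential-beam planned dose, Rician magnitude noise, scanner bias fields),
    voxelwise R2 relaxometry with reference-based inhomogeneity correction, linear
    R2-dose calibration with uncertainty and dose-resolution diagnostics, fiducial
    rigid registration and trilinear resampling, a 3D global gamma-index engine with
    per-slice pass-rate profiles and fail-region export, and dose-profile deficit
    statistics quantifying the underdose in the geometric shadow of a metal implant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
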