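Package: darklung
Title: Quantification of Ventilation-Dependent X-Ray Dark-Field Signal in Lungs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of grating-based X-ray dark-field
    thorax radiographs against CT-derived lung maps. Provides Hounsfield-unit
    lung segmentation with binary closing, conversion to water-relative
    attenuation, cone-beam forward projection of binary and masked volumes into
    projected lung thickness and water-equivalent height maps,
    polyoxymethylene-based beam-hardening correction of visibility reduction,
    a Compton-offset model for the regression intercept, shot-noise-weighted
    pixelwise linear regression yielding mean dark-field extinction
    coefficients and normalized scatter, tungsten-tube spectral simulation of
    effective water attenuation coefficients, noise-ratio and
    contrast-to-noise-ratio models, and a seeded digital thorax phantom that
    emulates the statistical structure of registered dark-field acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
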