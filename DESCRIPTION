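Package: besselflow
Title: Analysis of Bessel-Focus Volumetric Two-Photon Vascular Imaging
Version: 0.1.0
Authors@R: person("Vasc", "Imaging Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of volumetric two-photon fluorescence
    imaging of brain vasculature acquired with an axially extended Bessel
    focus. Includes an optics calculator for annular-aperture (Bessel) axial
    excitation profiles, a ground-truthed synthetic vascular phantom
    generator with flowing red-blood-cell shadows, vasomotion and
    arousal-coupled pupil dynamics, rigid registration and smoothing
    preprocessing, brightness- and threshold-based vessel size measurement,
    lagged ROI cross-correlation and pupil entrainment maps, infrared
    pupillometry by dark-region oval fitting, and 3D-corrected kymograph
    blood-flow velocimetry using Sobel filtering and iterative Radon
    transforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
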