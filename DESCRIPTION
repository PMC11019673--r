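Package: opmcal
Title: Calibration and Characterization Toolkit for Oblique Plane Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational pipeline for characterizing and calibrating an
    oblique plane microscope (OPM) built on a remote-focusing train: first-order
    design arithmetic for the remote-focusing optics, bead-based point spread
    function (PSF) measurement (focus selection by variance of Laplacian,
    a-trous B3-spline wavelet spot detection, 2D/1D Gaussian fit cascade),
    quantification of depth-dependent magnification distortion of the remote
    focusing volume, two-galvo scan voltage-ratio calibration from summed
    intensity slopes, and shear deskew of oblique scan volumes to cartesian
    coordinates. A synthetic bead-scene simulator with injected ground truth
    (anisotropic Gaussian PSF field, radial magnification distortion,
    scan-step-linear illumination gradient, Poisson and read noise) stands in
    for the instrument and supports recovery tests of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
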