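Package: ringdeconv
Title: Ring Deconvolution for Rotationally Symmetric Microscope Blur
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward modelling and deblurring for imaging systems whose
    point spread function varies only with distance from the optical
    axis.  Implements ring convolution, an exact FFT-based forward model
    for linear revolution-invariant systems, its TV-regularized
    least-squares inverse (ring deconvolution), single-image calibration
    of the five primary Seidel aberration coefficients from scattered
    point sources, blind spherical-aberration deconvolution by sharpness
    maximization, and the lateral-symmetry analogue (sheet convolution
    and deconvolution) for light-sheet microscopy volumes, together with
    seeded synthetic-data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
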