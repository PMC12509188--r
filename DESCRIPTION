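Package: thermopsf
Title: Vectorial Confocal Point Spread Functions and the Photothermal
    Nanolens Signal for Mid-Infrared Photothermal (O-PTIR) Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes vectorial focal-field components and confocal
    intensity point spread functions for high-NA objectives, including
    annular (Schwarzschild) apertures, and the steady-state photothermal
    "nanolens" signal of a small absorber heated by a modulated
    mid-infrared pump and probed by a focused visible beam.  The axial
    photothermal signal is evaluated both through a gamma-function /
    confluent-hypergeometric closed form and through an independent
    numerical Fresnel diffraction integral.  Includes resolution (FWHM)
    estimation, scan-image processing (tilt-rotation search, central-line
    averaging, Gaussian fits), a synthetic image generator, and
    least-squares recovery of the pump-probe focus offset and absorption
    cross section from axial scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
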