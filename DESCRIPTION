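Package: elastinv
Title: Quasi-Static Ultrasound Elastography and Mooney-Rivlin Inversion
    for Tumors in Layered Soft Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inversion pipeline for estimating the
    Mooney-Rivlin hyperelastic constants (C10, C01) of a tumor embedded in
    layered soft tissue from quasi-static ultrasound elastography data.
    Provides the uniaxial incompressible Mooney-Rivlin constitutive
    relations, a reduced layered forward solver for a three-material breast
    phantom under a low-frequency sinusoidal surface load, a convolutional
    radio-frequency (RF) speckle synthesizer, windowed normalized
    cross-correlation displacement tracking with guided search, and the
    iterative stress-strain regression algorithm that recovers (C10, C01)
    from axial displacements of a few tumor points, together with
    noise-injection evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
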