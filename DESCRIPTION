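Package: depspec
Title: Dielectrophoresis Spectroscopy of Functionalized Microspheres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for negative-dielectrophoresis (DEP)
    spectroscopy of ssDNA-functionalized polystyrene microspheres. Implements the
    Clausius-Mossotti factor and Stokes drift physics for a surface-conducting bead,
    a seeded synthetic generator of time-lapse microscope frames showing a bead band
    repelled from a convex electrode edge, sub-pixel band localization by
    thresholded intensity center of mass, frequency-swept drift-velocity spectra
    with replicate statistics and error-bar overlap tests, and nucleotide calling of
    measured spectra against a calibration library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
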