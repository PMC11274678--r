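Package: mwcompass
Title: Milky-Way-Based Visual Compass: Simulation, Motion Blur and
    Orientation Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the Milky Way as a celestial orientation
    cue for insect-inspired visual compasses. Renders synthetic night-sky
    images with a bright extended galactic band over a star field, generates
    random-walk motion-blur point-spread functions and applies them to
    images, estimates the band's axial orientation by Otsu thresholding and
    normalised second central moments, provides a Radon-transform baseline
    estimator, and runs seeded rotation benchmarks with axial error
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
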