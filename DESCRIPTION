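Package: doseweight
Title: Exposure Filtering and Motion Correction for Cryo-EM Movies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for handling radiation damage in electron cryo-microscopy
    movie data. Implements a resolution-dependent critical-exposure model,
    the matched-filter ("dose weighting") summation of movie frames that
    maximizes spectral signal-to-noise ratio, iterative rigid frame
    alignment with spline-smoothed drift trajectories, Fourier shell
    correlation utilities, and an estimation pipeline that recovers the
    critical-exposure curve from exposure-resolved FSC measurements.
    Includes a synthetic-movie generator with known ground truth for
    validation, MRC/MRCS movie input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
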