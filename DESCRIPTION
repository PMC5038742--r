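Package: stepfall
Title: Stochastic Detection of Steps and Falls from Tri-Axial Accelerometer Traces
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects atomic human movements (single steps, falls) in
    uniformly sampled tri-axial accelerometer recordings using per-cadence
    Gaussian models of window max/min amplitude and timing features, a
    two-sided exponential null-class model, and a Bayesian speed posterior.
    Includes gravity estimation by moving average, vertical/longitudinal
    projection, torso-location amplitude compensation, fall detection via
    peak-normalised Gaussian kernel products with thresholding, fall
    classification into frontal-walking, frontal-sitting and other falls,
    periodic post-correction of missed steps, a seeded synthetic trace
    generator calibrated to published model parameters, CSV/JSON I/O and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
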