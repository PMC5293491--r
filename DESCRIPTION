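Package: lcpipe
Title: Quantitative Pipeline for Lobula Columnar Neuron Behavior and Imaging Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying visually guided and optogenetically evoked
    behavior of Drosophila lobula columnar (LC) visual projection neurons and
    their calcium responses. Includes a looming-stimulus synthesizer on a
    modeled LED display (constant-approach-velocity expansion, luminance-matched
    scramble controls, translating objects), body-frame kinematics from tracked
    trajectories with Savitzky-Golay angular velocity, percentile-threshold
    behavioral classification with penetrance statistics and exact binomial
    confidence intervals, a two-photon calcium dF/F pipeline (rigid
    cross-correlation motion compensation, sliding-percentile baseline,
    per-fly normalization), an eye-geometry arbor-coverage estimator, and
    synthetic-data generators with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
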