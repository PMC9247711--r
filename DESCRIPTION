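Package: axontools
Title: Analysis of Long-Range Axon Calcium Imaging During Go/No-Go Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying two-photon calcium imaging of long-range
    axonal boutons recorded in visual cortex while head-fixed mice perform a
    go/no-go visual discrimination task. Covers sliding-percentile delta-F/F
    baseline estimation, correlation-based bouton-to-axon merging and
    cross-channel bleed-through quality control, trial-modulation
    classification and event-triggered response testing with false discovery
    rate control, signal-detection d-prime and correctness linear models,
    circular-shift permutation tests for lick-correlated activity, rewarded
    versus unrewarded lick comparisons and the reward-targeting index,
    constrained double-Gaussian direction tuning with orientation and
    direction selectivity indices, and landmark-based pupil ellipse
    geometry. A synthetic session generator with known ground truth supports
    calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rhdf5,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
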