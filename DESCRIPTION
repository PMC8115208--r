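Package: stridefield
Title: Lateral Foot-Placement Control Analysis for Treadmill Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of step-to-step coordination between the lateral
    center-of-mass (COM) state and lateral foot placement during treadmill
    walking. Reads and filters 3D marker trajectories, detects gait events
    from calcaneus and 5th-metatarsal vertical positions, estimates the
    lateral COM state from a four-marker pelvis segment, fits the
    foot-placement regression at every 2% of the preceding swing phase to
    produce R-squared time-series, computes step-width metrics, and performs
    one-dimensional statistical parametric mapping (random field theory
    thresholds) over the 51-node swing grid. Includes a frontal-plane
    inverted-pendulum walker simulator with a configurable COM-state
    feedback law and a lateral velocity-damping force field, providing
    synthetic marker data with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
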