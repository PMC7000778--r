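Package: slipgait
Title: Spring-Mass Analysis of Treadmill Sprinting with Asymmetric Legs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measurement-and-analysis chain for treadmill running trials:
    zero-phase Butterworth filtering of ground reaction forces, threshold
    based ground-contact detection, per-step spatiotemporal and force
    metrics, spring-mass (SLIP) leg stiffness estimation from contact
    angle and double-integrated centre-of-mass displacement, between-leg
    symmetry indices, and the mixed-model statistics used to compare
    running-specific prosthesis configurations. Includes a two-leg
    spring-loaded inverted pendulum simulator that generates steady
    asymmetric running sessions with known ground truth, so every
    pipeline stage can be verified without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    deSolve,
    lme4,
    lmerTest,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
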