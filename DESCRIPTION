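Package: liftlab
Title: Simulation and Analysis of Grasp-and-Lift Force Scaling and Weight
    Perception Experiments
Version: 0.1.0
Authors@R: person("Lift", "Lab", email = "liftlab@example.org",
    role = c("aut", "cre"))
Description: Tools for psychophysics experiments in which participants
    repeatedly grasp and lift objects of different weights while grip and
    load forces are recorded from fingertip force sensors.  Provides a
    pseudorandom session designer with dummy-trial bookkeeping, a synthetic
    generator of two-sensor fingertip force traces and self-scaled weight
    reports with sensorimotor-memory structure, zero-phase Butterworth
    filtering and lift-event detection, force-rate peak extraction, weight
    report standardisation, and the full inference protocol: mixed-design
    repeated-measures ANOVA with Mauchly/Greenhouse-Geisser handling and a
    location-split rule, Bonferroni post hocs, AR(1) linear mixed models
    relating force scaling to perception, and Fisher-z Pearson correlation
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
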