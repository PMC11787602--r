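Package: somatten
Title: Somatosensory Attenuation During Reaching: Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses force-discrimination experiments that probe
    how the perceived intensity of touch on a static hand changes across the
    phases of the other hand's reaching movement toward it. Provides a
    synthetic-data generator (trial schedules, minimum-jerk reaching
    kinematics at 240 Hz, a logistic observer whose point of subjective
    equality shifts with reach phase), velocity-based movement segmentation
    and phase binning, trial- and participant-level quality control with an
    audit log, logistic psychometric fitting (PSE, JND, McFadden pseudo-R2),
    and the group-level inference layer: repeated-measures and mixed ANOVA
    with Greenhouse-Geisser correction, normality-gated planned comparisons
    with FDR correction and matched effect sizes, per-participant linear
    attenuation slopes, and one-sided default Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
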