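Package: costim
Title: Linearity Analysis of Forces Evoked by Combined Spinal and Muscle Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.com")
Description: Tools for testing whether hindlimb isometric forces evoked by
    simultaneous epidural spinal cord and intramuscular stimulation equal the
    linear vector sum of the forces evoked by each site alone. Provides a
    synthetic-data generator emulating blocked co-stimulation experiments
    (sigmoid recruitment curves, direction rotation with amplitude,
    site-specific trial-to-trial variability, optional nonlinear interaction
    and fatigue drift), force-trace baseline subtraction and window averaging,
    prediction/magnitude/direction/relative error metrics with circular
    dispersion statistics, linear mixed-effects contrasts of error by
    co-stimulation type, and a resampling procedure that builds the
    distribution of prediction errors expected under exact linear summation
    given the observed trial-to-trial variability.
License: MIT
Encoding: UTF-8
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
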