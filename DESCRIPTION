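Package: gazesal
Title: Sensory Salience Processing in Naturalistic Gaze and Pupillometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing naturalistic eye-tracking
    data with respect to sensory salience: velocity-threshold fixation and
    saccade detection on raw binocular gaze streams, spectral-residual
    physical-salience and Gaussian-mixture motion-salience maps computed from
    video frames, Rec.709 luminance estimation, gaze-to-map and
    area-of-interest matching, pupillary-response extraction with temporal
    decomposition by principal components with varimax rotation, and a linear
    mixed-model inference stage with Satterthwaite tests, FDR adjustment,
    marginal contrasts and simulation-based power. Includes a synthetic-data
    generator that plants known fixations, salient patches, pupil dynamics
    and cohort-level effects so every stage can be validated against ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
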