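Package: microdyn
Title: EEG Microstate Temporal Dynamics and Wrist Actigraphy for Stroke Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for resting-state EEG microstate temporal
    dynamics and bilateral wrist-actigraphy spontaneous arm movement in
    middle-cerebral-artery stroke cohorts. Provides a synthetic-data
    generator (template-map EEG with semi-Markov state dynamics, paired
    per-minute activity-count series with controlled correlation and
    asymmetry), EEG preprocessing (notch and zero-phase Butterworth
    band-pass filtering, robust bad-channel detection, spherical-spline
    interpolation, average referencing, epoch selection), polarity-invariant
    modified k-means microstate segmentation with global-field-power peak
    extraction, back-fitting and temporal parameters (coverage, duration,
    occurrence, transition probabilities), actigraphy asymmetry metrics
    (upper-limb activity ratio, bimanual coordination index, moderate
    activity minutes), and a covariate-adjusted group comparison layer with
    effect sizes and false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
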