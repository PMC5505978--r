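Package: rrgamma
Title: Induced RR-Interval Time Series and the Gamma Separation Metric
    for Heart Rhythm Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing heart rhythm from inter-beat (RR)
    interval tachograms. Builds induced time series (forward
    finite-difference time derivatives of the tachogram up to order 10),
    reduces them to mean/standard-deviation state variables, quantifies
    two-group discriminability with a normalized surface-to-surface
    ellipsoid distance (the gamma metric), exhaustively ranks variable
    subsets by discriminative power, and classifies normal sinus rhythm
    versus atrial fibrillation with unregularized logistic regression,
    including short observation-window sweeps. Includes beat-timing
    perturbation models (timing uncertainty, missing beats, premature
    atrial and ventricular contractions) and calibrated synthetic NSR/AF
    tachogram generators for fully reproducible, data-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
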