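Package: gaitcwt
Title: Wavelet-Based Gait Event Detection from a Lower-Back Inertial
    Measurement Unit
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects heel-strike and toe-off gait events from the
    anterior-posterior acceleration of a single lower-back inertial
    measurement unit using single-scale continuous wavelet transform
    differentiation, with a turning-aware variant for unconstrained
    (home-like) recordings that switches wavelet families inside and
    outside gyroscope-detected turns.  Includes a synthetic gait signal
    generator with exact ground truth, event matching against reference
    systems, contingency-table agreement statistics (sensitivity,
    specificity, Cohen's kappa, predictive values), Bland-Altman limits
    of agreement, intraclass correlation for rater agreement, and a
    command-line interface covering simulation, detection, turn
    segmentation and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
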