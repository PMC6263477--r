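Package: crackler
Title: Automated Detection of Respiratory Crackles via Time-Varying
    Autoregressive Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects discontinuous adventitious lung sounds (crackles) in
    maneuver-guided respiratory sound recordings. Recordings are bandpass
    filtered (75-1000 Hz) and amplitude normalized, modeled sample-by-sample
    with a fourth-order time-varying autoregressive (TVAR) process estimated
    by recursive least squares with a constant forgetting factor, and crackle
    onsets are localized from abrupt changes in the coefficient trajectories
    using a windowed derivative-threshold rule. Includes a synthetic crackle
    simulator (fine and coarse waveforms, phase-targeted insertion scenarios
    with exact ground truth), a surrogate basal breath-sound generator,
    sensitivity/specificity/accuracy scoring with onset matching, and
    ROC-based threshold selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
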