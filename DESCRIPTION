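Package: icualert
Title: Dynamic Landmark Competing-Risk Prediction of ICU-Acquired Infection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark dynamic prediction of ICU-acquired infection (ICU-AI)
    with death and ICU discharge as competing risks. Provides a synthetic
    ICU cohort generator (recurrent infection onsets with a 48-hour
    post-onset blackout, per-patient frailty on terminal-event hazards,
    8-hourly clinical series with pre-onset drift, and 1-minute vital-sign
    streams carrying a pre-onset deterioration signature), a stacked
    landmark dataset builder on an 8-hourly grid with a sliding 24- or
    48-hour prediction window, a cause-specific Cox landmark supermodel
    with cumulative-incidence predictions, a 1-D convolutional network
    risk score trained on vital-sign windows, and a dynamic evaluation
    suite (per-landmark Harrell c-index under administrative censoring of
    competing events, Brier score, competing-risk calibration, Wald and
    permutation importance heatmaps, and alert lead-time analysis), all
    orchestrated by a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    zoo,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
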