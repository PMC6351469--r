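Package: posturogaze
Title: Oculo-Postural Coupling Analysis for Small Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the coupling between oculomotor behaviour and
    postural control in small clinical cohorts. Irregularly sampled
    centre-of-pressure recordings from a force platform are resampled to a
    uniform grid (sliding-window average with interpolation fallback), local
    time windows are classified as quiet or unquiet sway with a two-component
    Gaussian mixture, and a 0-100 postural score is derived from the unquiet
    fraction under eyes-open and eyes-closed conditions. Gaze recordings are
    segmented into fixations and saccades with a velocity-threshold (I-VT)
    classifier and summarised into eighteen oculomotor biomarkers. A bespoke
    random-forest regressor provides out-of-bag permutation importance
    (mean-over-sd of per-tree error changes), quartile-threshold feature
    selection, and leave-one-out prediction of the postural score with
    normalised RMSE. A seeded synthetic-cohort generator with a latent
    severity that jointly drives gaze statistics and sway burstiness makes
    every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
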