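Package: mermap
Title: Microelectrode Recording Analysis for Subthalamic Nucleus Mapping
Version: 0.1.0
Authors@R:
    person("MER", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for intraoperative microelectrode recordings
    (MER) acquired during deep brain stimulation surgery targeting the
    subthalamic nucleus.  Provides variance-coefficient artifact rejection
    with monotone-cubic gap bridging, amplitude-threshold spike detection,
    Haar-wavelet feature extraction with Lilliefors coefficient selection,
    superparamagnetic clustering of spike shapes, background-activity
    reconstruction, a battery of spike-train and Welch band-power features,
    and maximum-parameter prediction of target depth and trajectory with
    accuracy, ROC/AUC and correlation evaluation.  Includes a synthetic
    Ben's-Gun session generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
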