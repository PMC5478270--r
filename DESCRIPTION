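Package: threatconn
Title: Threat-of-Shock Brain Connectivity and Oscillatory Analysis with
    Synthetic Cohorts
Version: 0.1.0
Authors@R: person("threatconn", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis chain for threat-of-shock experiments: fMRI global
    brain connectivity (GBC) and seed-based connectivity with motion and
    shock censoring, autocorrelation-matched Monte-Carlo cluster-size
    thresholds, MEG multitaper spectral analysis with individual alpha
    frequency detection, DICS beamformer source projection with
    permutation cluster statistics, and startle eyeblink EMG / continuous
    anxiety rating scoring.  A synthetic-cohort generator reproduces the
    alternating safe/threat block design with known injected effects so
    every stage of the pipeline can be validated without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rhdf5
Config/testthat/edition: 3
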