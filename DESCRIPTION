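Package: rmdnet
Title: Directed Functional EEG Networks from a Recurrence-Based Measure of Dependence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed, event-locked functional networks from
    multichannel EEG band-power envelopes using a lagged recurrence-based
    measure of dependence (RMD). Provides Morlet wavelet band-power
    extraction for alpha (8-12 Hz) and beta (15-30 Hz) bands, trial
    segmentation and reaction-time-based condition assignment for
    perceptual decision-making experiments, per-link paired testing with
    max-statistic permutation correction, graph metrics over the resulting
    increasing/decreasing link networks, and the network-formation timeline
    (t1, t2, t3) relating network reconfiguration to reaction time. A
    synthetic-data generator with planted lagged envelope couplings
    provides ground truth for parameter-recovery validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
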