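Package: mesaclip
Title: Harmonic-Artifact-Free Time-Frequency Analysis of Spiky Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Continuous wavelet analysis for spike-train-like
    electrophysiological signals (e.g. smooth-muscle EMG). Implements the
    mesaclip algorithm, which clips wavelet-amplitude peaks spanning fewer
    than k phase cycles so that the non-sinusoidal shape of individual
    spikes no longer injects harmonic artifacts into the time-frequency
    representation, while the repetition frequency of the spike train is
    retained. Includes generalized Morse wavelets with a harmonic-nulling
    calibration of the time-bandwidth parameter, synchrosqueezing as an
    optional post-process, a seedable simulator of log-normal inverse-ISI
    spike trains with pink noise, a threshold-crossing peak-detection
    baseline, and a benchmark comparing frequency estimators across noise
    and regularity conditions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
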