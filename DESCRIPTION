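Package: hfbdeconv
Title: Deconvolution of Blink- and Gap-Related High-Frequency Broadband
    Responses in Intracranial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how eye blinks and brief external stimulus
    interruptions ("gaps") modulate the 70-150 Hz high-frequency broadband
    (HFB) envelope of intracranial field potentials. Provides HFB extraction
    from raw multichannel recordings (eight-band Hilbert envelope, outlier
    rejection, percent-signal-change normalisation), blink detection and
    timing from pupil and EOG traces, finite-impulse-response (FIR)
    deconvolution of overlapping event-related responses with HC3
    heteroskedasticity-consistent standard errors, quantification of
    disappearance-related activation dips and reappearance-related overshoots
    as extreme contiguous-cluster integrals with split-half (non-circular)
    estimation, stratified permutation tests and a randomization test of
    independence, latency/duration event matching, and a synthetic-session
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    lmtest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
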