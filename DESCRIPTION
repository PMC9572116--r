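Package: fmcwvitals
Title: Non-Contact Vital-Sign Extraction from FMCW Millimeter-Wave Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing chain for estimating respiration and heart rate
    from the slow-time phase of a frequency-modulated continuous-wave (FMCW)
    millimeter-wave radar. Provides a ground-truth-labelled radar I/Q simulator
    (chest-displacement beat-signal model with clutter, DC offset, phase noise
    and impulse artifacts), range-FFT preprocessing with static clutter removal,
    DC-offset compensation by non-linear least-squares circle fitting, extended
    differentiate-and-cross-multiply (DACM) phase demodulation, an iterative
    variational-mode-decomposition (VMD) wavelet-interval-thresholding impulse
    denoiser, and a dual-estimator (FFT with chirp-z spectral zoom versus
    time-domain peak seeking) heart-rate decision rule with confidence
    thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
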