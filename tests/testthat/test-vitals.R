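test_that("separate_vitals assigns breathing and heart modes from a two-tone phase", {
  tt <- two_tone()
  sep <- separate_vitals(tt$x, fs = 20)
  expect_equal(sep$breath_freq, 0.3, tolerance = 0.05 / 0.3)
  expect_equal(sep$heart_freq, 1.2, tolerance = 0.05 / 1.2)
  expect_gt(cor(sep$breathing, tt$tone1), 0.9)
  expect_gt(cor(sep$heart, tt$tone2), 0.9)

  expect_error(separate_vitals(numeric(64), fs = 20), "band")
})

test_that("elliptic bandpass meets its design response", {
  fs <- 20
  flt <- signal::ellip(5, 0.5, 40, c(0.7, 3.3) / 10, type = "pass")
  H <- function(f) {
    w <- 2 * pi * f / fs
    Mod(sum(flt$b * exp(-1i * w * (seq_along(flt$b) - 1))) /
        sum(flt$a * exp(-1i * w * (seq_along(flt$a) - 1))))^2 # |H|^2: two passes
  }
  expect_gt(H(1.2), 10^(-0.6 / 10)) # within the configured passband ripple
  expect_lt(H(1.2), 1.01)
  expect_lt(10 * log10(H(0.25)), -39.5) # configured stopband attenuation

  # applied to signals: zero in, zero out; tone passes at ~unit gain
  expect_equal(bandpass_heart(numeric(255), fs), numeric(255))
  t <- (0:254) / fs
  y <- bandpass_heart(sin(2 * pi * 1.2 * t), fs)
  expect_equal(sd(y) * sqrt(2), 1, tolerance = 0.15)
  expect_error(bandpass_heart(rnorm(64), fs = 6), "too low")
})

test_that("notch bank attenuates harmonics, spares off-notch tones, skips Nyquist", {
  fs <- 20
  t <- (0:254) / fs
  f_resp <- 0.35
  tone <- function(f) sin(2 * pi * f * t)
  g <- function(f) {
    y <- notch_harmonics(tone(f), fs, f_resp)
    20 * log10(sd(y) / sd(tone(f)))
  }
  # a 12.8 s record limits the removable fraction of a tone to its own
  # spectral line width; the Q = 6 notch takes out most of it
  expect_lt(g(2 * f_resp), -7)
  expect_gt(g(1.3 * f_resp), -1) # off-notch tone within 1 dB

  expect_equal(notch_harmonics(numeric(255), fs, f_resp), numeric(255))
  expect_warning(notch_harmonics(tone(1), fs, f_resp = 3), "Nyquist")
  expect_error(notch_harmonics(tone(1), fs, f_resp = -1), "positive")
})

test_that("fft_czt_rate refines a tone to millihertz accuracy", {
  fs <- 20
  t <- (0:255) / fs
  est <- fft_czt_rate(sin(2 * pi * 0.30 * t), fs, c(0.1, 0.7))
  expect_equal(est$peak_freq, 0.30, tolerance = 0.002 / 0.3)

  # refinement never strays more than one coarse bin from the coarse peak
  withr::with_seed(2, x <- rnorm(256))
  e2 <- fft_czt_rate(x, fs, c(0.7, 3.3))
  expect_lte(abs(e2$peak_freq - e2$freqs[e2$peak_index]), fs / 256)

  # the stronger of two in-band tones wins
  e3 <- fft_czt_rate(2 * sin(2 * pi * 1.0 * t) + sin(2 * pi * 2.0 * t),
                     fs, c(0.7, 3.3))
  expect_equal(e3$peak_freq, 1.0, tolerance = 0.01)

  # zoom equals a brute-force DTFT evaluated on the same grid
  sig <- sin(2 * pi * 1.23 * t)
  e4 <- fft_czt_rate(sig, fs, c(0.7, 3.3))
  brute <- sapply(e4$zoom_freqs, function(f) {
    Mod(sum(sig * exp(-2i * pi * f * t)))
  })
  expect_equal(e4$zoom_amps, brute, tolerance = 1e-9)

  expect_error(fft_czt_rate(sig, fs, c(3, 1)), "lo < hi")
  expect_error(fft_czt_rate(sig, fs, c(0, 5)), "inside")
})

test_that("peak seeking counts clean maxima and rejects spikes", {
  fs <- 20
  t <- seq(0, 12.8 - 1 / fs, by = 1 / fs) # 256 samples
  out <- peak_seek_rate(sin(2 * pi * 1.25 * t), fs, duration = 12.8)
  expect_equal(out$n_peaks, 16)
  expect_equal(out$fh, 1.25)

  # Np / duration arithmetic
  expect_equal(peak_seek_rate(sin(2 * pi * 1.25 * t), fs, duration = 12.8)$fh,
               16 / 12.8)

  # an isolated spike with non-monotone flanks is not counted
  x <- rep(0.0, 40)
  x[20] <- 5
  expect_equal(peak_seek_rate(x, fs)$n_peaks, 0)

  expect_error(peak_seek_rate(1:4, fs), "5 samples")
})

test_that("spectral confidence matches closed forms", {
  mk <- function(amps) {
    structure(list(freqs = seq_along(amps), amps = amps,
                   peak_index = which.max(amps), peak_freq = which.max(amps),
                   method = "fft_czt"),
              class = "spectrum_estimate")
  }
  M <- 40
  uniform <- mk(rep(1, M))
  uniform$peak_index <- 10L # interior line of a flat spectrum
  expect_equal(fft_confidence(uniform), 3 / (M - 3))
  # all energy in the three peak lines -> sentinel
  expect_equal(fft_confidence(mk(c(0, 1, 2, 1, rep(0, 10)))), 1e12)

  # a windowed tone concentrates energy: higher confidence than white noise
  t <- (0:255) / 20
  tone_sp <- fft_czt_rate(sin(2 * pi * 1.5 * t) * signal::hanning(256), 20, c(0.7, 3.3))
  withr::with_seed(4, noise <- rnorm(256))
  noise <- noise * sqrt(sum((sin(2 * pi * 1.5 * t) * signal::hanning(256))^2) / sum(noise^2))
  noise_sp <- fft_czt_rate(noise, 20, c(0.7, 3.3))
  expect_gt(fft_confidence(tone_sp), fft_confidence(noise_sp))
})

test_that("the three-tier heart decision behaves per its contract", {
  # decisive confidence: FFT trusted regardless of disagreement
  d <- decide_heart_rate(1.7188, 2.7029, s_fft = 5)
  expect_equal(d$final, 1.7188)
  expect_equal(d$chosen, "fft_czt")

  # moderate confidence + agreement: FFT
  d <- decide_heart_rate(1.45, 1.40, s_fft = 0.5)
  expect_equal(d$final, 1.45)

  # moderate confidence + disagreement: peek
  d <- decide_heart_rate(1.45, 1.80, s_fft = 0.5)
  expect_equal(d$final, 1.80)
  expect_equal(d$chosen, "peek")

  # low confidence: peek regardless
  d <- decide_heart_rate(1.45, 1.46, s_fft = 0.1)
  expect_equal(d$final, 1.46)

  # purity: same inputs, same outputs
  expect_identical(decide_heart_rate(1.2, 1.3, 0.4),
                   decide_heart_rate(1.2, 1.3, 0.4))
})

test_that("relative error and spectral SNR match their closed forms", {
  expect_equal(relative_error(1.0989, 66), 0.1, tolerance = 0.05)
  expect_equal(relative_error(1.2, 72), 0)
  expect_equal(round(relative_error(1.9373, 120), 2), 3.14, tolerance = 0.005)
  expect_error(relative_error(1, 0), "positive")

  M <- 32
  expect_equal(snr_metric(rep(1, M), 10), 10 * log10(3 / (M - 3)))
  # equal split between the 3 peak lines and the rest: 0 dB
  expect_equal(snr_metric(c(1, 1, 1, sqrt(3)), 2), 0)
  expect_error(snr_metric(rep(1, 8), 1), "edge")
  sat <- snr_metric(c(0, 1, 1, 1, 0, 0), 3)
  expect_true(is.infinite(sat) && isTRUE(attr(sat, "saturated")))
})

test_that("bundled decision records are internally consistent where flagged", {
  rec <- heart_decision_records()
  expect_equal(nrow(rec), 22)
  # every adjudication equals one of the two estimates
  expect_true(all(abs(rec$judgment - rec$f_fft_czt) < 1e-9 |
                  abs(rec$judgment - rec$f_peek) < 1e-9))
  # the known swapped/rounded rows are the only error-inconsistent ones
  expect_equal(sum(!rec$error_consistent), 3)
  # all adjudications are attainable under the decision logic
  expect_true(all(rec$rule_consistent))
  # published errors of self-consistent rows reproduce at printed precision
  cons <- rec[rec$error_consistent, ]
  expect_true(all(abs(relative_error(cons$judgment, cons$ref_bpm) -
                      cons$printed_error_pct) <= 0.005 + 1e-9))
})
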