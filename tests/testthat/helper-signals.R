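# shared fixtures, all generated in code

fs_slow <- 20

two_tone <- function(n = 255, f1 = 0.3, f2 = 1.2, a1 = 0.3, a2 = 0.15,
                     fs = fs_slow) {
  t <- (0:(n - 1)) / fs
  list(t = t, x = a1 * sin(2 * pi * f1 * t) + a2 * sin(2 * pi * f2 * t),
       tone1 = a1 * sin(2 * pi * f1 * t), tone2 = a2 * sin(2 * pi * f2 * t))
}

# default simulated subject used across tests (realistic resting vitals)
test_cube <- function(seed = 1, breath_freq = 0.3, heart_freq = 1.2,
                      n_frames = 256L, noise = TRUE) {
  cfg <- radar_config(n_frames = n_frames)
  motion <- chest_motion(R0 = 1.0, breath_amp = 1e-3, breath_freq = breath_freq,
                         heart_amp = 1e-4, heart_freq = heart_freq)
  imp <- if (noise) {
    impairment_model(dc_i = 0.3, dc_q = -0.2, phase_noise_std = 0.02,
                     awgn_std = 0.05, impulse_rate = 0.012, impulse_amp = 1.5,
                     clutter = list(c(0.4, 0.5)), seed = seed)
  } else {
    impairment_model(seed = seed)
  }
  simulate_cube(cfg, motion, imp)
}

# one-sided spectral SNR at the peak nearest f0 (Eq.-style 3-line metric)
snr_at_tone <- function(x, f0, fs = fs_slow, halfwidth = 0.15) {
  n1 <- length(x) %/% 2 + 1
  freqs <- (0:(n1 - 1)) * fs / length(x)
  amps <- abs(fft(x)[1:n1])
  band <- which(freqs >= f0 - halfwidth & freqs <= f0 + halfwidth)
  snr_metric(amps, band[which.max(amps[band])])
}

# analytic beat-frequency bin for a reflector at range R
beat_bin <- function(cfg, R, n_fft = cfg$n_samples) {
  round(2 * cfg$slope * R / 299792458 * n_fft / cfg$Fs)
}
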