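#' Radar chirp and frame timing configuration
#'
#' Bundles the FMCW waveform parameters that the whole pipeline depends on.
#' The defaults are the 77 GHz sensor settings used throughout the package:
#' chirp start frequency 77 GHz, chirp duration 50 us, slope 80 MHz/us
#' (sweep bandwidth 4 GHz), ADC rate 6.4 Msps, frame period 50 ms (slow-time
#' sampling rate 20 Hz), 256 fast-time samples per chirp and 256 frames
#' (12.8 s observation), one chirp per frame.
#'
#' @param fc Chirp starting frequency (Hz).
#' @param Tc Chirp duration (s).
#' @param slope Chirp slope K (Hz/s).
#' @param Fs ADC sampling rate (samples/s).
#' @param Ts Frame period (s); the slow-time sampling rate is `1/Ts`.
#' @param n_samples Fast-time samples recorded per chirp.
#' @param n_frames Number of frames (slow-time length).
#'
#' @return An object of class `radar_config` with the above fields plus the
#'   derived carrier wavelength `lambda_max = c/fc` (m), the full sweep
#'   bandwidth `bandwidth = slope * Tc` (Hz) and the effective sampled
#'   bandwidth `bandwidth_eff = slope * n_samples / Fs` (Hz) that sets the
#'   range resolution.
#' @examples
#' cfg <- radar_config()
#' cfg$bandwidth / 1e9   # 4 GHz sweep
#' cfg$n_frames * cfg$Ts # 12.8 s observation
#' @export
radar_config <- function(fc = 77e9, Tc = 50e-6, slope = 80e12,
                         Fs = 6.4e6, Ts = 50e-3,
                         n_samples = 256L, n_frames = 256L) {
  vals <- c(fc = fc, Tc = Tc, slope = slope, Fs = Fs, Ts = Ts,
            n_samples = n_samples, n_frames = n_frames)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all radar_config parameters must be positive and finite")
  }
  if (n_samples / Fs > Tc + 1e-12) {
    stop("fast-time sampling window n_samples/Fs exceeds the chirp duration Tc")
  }
  structure(list(
    fc = fc, Tc = Tc, slope = slope, Fs = Fs, Ts = Ts,
    n_samples = as.integer(n_samples), n_frames = as.integer(n_frames),
    lambda_max = C_LIGHT / fc,
    bandwidth = slope * Tc,
    bandwidth_eff = slope * n_samples / Fs
  ), class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  fc = %.4g GHz, slope = %.4g MHz/us, Tc = %.4g us\n",
              x$fc / 1e9, x$slope / 1e12, x$Tc * 1e6))
  cat(sprintf("  Fs = %.4g Msps, %d samples/chirp, %d frames @ Ts = %.4g ms\n",
              x$Fs / 1e6, x$n_samples, x$n_frames, x$Ts * 1e3))
  cat(sprintf("  sweep bandwidth %.4g GHz (effective %.4g GHz), lambda %.4g mm\n",
              x$bandwidth / 1e9, x$bandwidth_eff / 1e9, x$lambda_max * 1e3))
  invisible(x)
}

#' Chest-motion (vital-sign displacement) model
#'
#' Parametrises the sub-millimetre chest-wall displacement x(t) whose phase
#' modulation the radar observes: a breathing fundamental with optional
#' harmonics plus a heartbeat sinusoid,
#' \deqn{x(t) = A_b \sum_h c_h \sin(2\pi h f_b t + \phi_b) + A_h \sin(2\pi f_h t + \phi_h)}
#' with \eqn{c_1 = 1} and `harmonic_coeffs` giving \eqn{c_2..c_4}.
#'
#' Typical resting values: breathing 0.2--0.5 Hz with amplitude ~1 mm,
#' heartbeat 1--1.8 Hz with amplitude ~0.1 mm.
#'
#' @param R0 Standoff range of the subject (m).
#' @param breath_amp,breath_freq Breathing displacement amplitude (m) and rate (Hz).
#' @param heart_amp,heart_freq Heartbeat displacement amplitude (m) and rate (Hz).
#' @param harmonic_coeffs Relative amplitudes of breathing harmonics 2--4.
#' @param breath_phase,heart_phase Phase offsets (rad).
#' @return An object of class `chest_motion`.
#' @examples
#' m <- chest_motion(breath_freq = 0.3, heart_freq = 1.2)
#' x <- chest_displacement(m, seq(0, 10, by = 0.05))
#' @export
chest_motion <- function(R0 = 1.0,
                         breath_amp = 1e-3, breath_freq = 0.3,
                         heart_amp = 1e-4, heart_freq = 1.2,
                         harmonic_coeffs = c(0.2, 0.1, 0.05),
                         breath_phase = 0, heart_phase = 0) {
  if (R0 <= 0) stop("R0 must be positive")
  if (breath_amp < 0 || heart_amp < 0 || any(harmonic_coeffs < 0)) {
    stop("displacement amplitudes must be non-negative")
  }
  if (heart_amp > breath_amp && breath_amp > 0) {
    warning("heart_amp exceeds breath_amp: outside the typical physiological regime")
  }
  structure(list(
    R0 = R0, breath_amp = breath_amp, breath_freq = breath_freq,
    heart_amp = heart_amp, heart_freq = heart_freq,
    harmonic_coeffs = harmonic_coeffs,
    breath_phase = breath_phase, heart_phase = heart_phase
  ), class = "chest_motion")
}

#' Radar impairment model
#'
#' Collects the non-ideal effects applied by [simulate_cube()]: per-channel DC
#' offsets, per-frame Gaussian phase noise on I and Q (independent draws),
#' additive white Gaussian noise, impulse artifacts in slow time and static
#' clutter reflectors. `seed` fixes the full noise realisation so a simulated
#' cube is bit-reproducible.
#'
#' @param dc_i,dc_q DC offset added to the I/Q channels (amplitude units).
#' @param phase_noise_std Std. dev. of the per-frame phase noise (rad).
#' @param awgn_std Std. dev. of additive white Gaussian noise per channel.
#' @param impulse_rate Impulse events per slow-time sample (the number of
#'   corrupted frames is `round(impulse_rate * n_frames)`).
#' @param impulse_amp Amplitude of each impulse event.
#' @param clutter List of static reflectors, each `c(range_m, amplitude)`.
#' @param seed Integer seed fixing the realisation.
#' @return An object of class `impairment_model`.
#' @export
impairment_model <- function(dc_i = 0, dc_q = 0,
                             phase_noise_std = 0, awgn_std = 0,
                             impulse_rate = 0, impulse_amp = 0,
                             clutter = list(), seed = 1L) {
  if (phase_noise_std < 0 || awgn_std < 0 || impulse_rate < 0 || impulse_amp < 0) {
    stop("noise magnitudes must be non-negative")
  }
  if (!is.list(clutter)) stop("clutter must be a list of c(range, amplitude) pairs")
  structure(list(
    dc_i = dc_i, dc_q = dc_q,
    phase_noise_std = phase_noise_std, awgn_std = awgn_std,
    impulse_rate = impulse_rate, impulse_amp = impulse_amp,
    clutter = clutter, seed = as.integer(seed)
  ), class = "impairment_model")
}

#' Raw I/Q frame matrix (radar data cube)
#'
#' Thin container for the complex fast-time x slow-time matrix produced by the
#' simulator or read from disk. Columns are chirps (frames), rows are
#' fast-time ADC samples.
#'
#' @param data Complex matrix `n_samples x n_frames`.
#' @param config The [radar_config()] the data were produced under.
#' @param truth Optional [chest_motion()] ground-truth tag.
#' @return An object of class `iq_cube`.
#' @export
iq_cube <- function(data, config, truth = NULL) {
  stopifnot(is.matrix(data), inherits(config, "radar_config"))
  if (nrow(data) != config$n_samples || ncol(data) != config$n_frames) {
    stop(sprintf("cube dimensions %d x %d do not match config %d x %d",
                 nrow(data), ncol(data), config$n_samples, config$n_frames))
  }
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data)))) {
    stop("cube contains non-finite entries")
  }
  structure(list(data = data, config = config, truth = truth),
            class = "iq_cube")
}

#' @export
print.iq_cube <- function(x, ...) {
  cat(sprintf("<iq_cube> %d fast-time samples x %d frames (%.3g s)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) * x$config$Ts))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: breathing %.3g Hz, heart %.3g Hz at R0 = %.3g m\n",
                x$truth$breath_freq, x$truth$heart_freq, x$truth$R0))
  }
  invisible(x)
}
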