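#' Chest displacement waveform
#'
#' Evaluates the displacement model of [chest_motion()] on a time grid:
#' breathing fundamental plus configured harmonics plus heartbeat sinusoid.
#'
#' @param motion A [chest_motion()] object.
#' @param t Monotonically increasing time grid (s).
#' @return Numeric displacement series (m), same length as `t`.
#' @export
chest_displacement <- function(motion, t) {
  stopifnot(inherits(motion, "chest_motion"))
  if (length(t) == 0) stop("time grid is empty")
  if (length(t) > 1 && any(diff(t) <= 0)) stop("time grid must be monotone increasing")
  x <- motion$breath_amp * sin(2 * pi * motion$breath_freq * t + motion$breath_phase)
  ch <- motion$harmonic_coeffs
  for (h in seq_along(ch)) {
    x <- x + motion$breath_amp * ch[h] *
      sin(2 * pi * (h + 1) * motion$breath_freq * t + motion$breath_phase)
  }
  x + motion$heart_amp * sin(2 * pi * motion$heart_freq * t + motion$heart_phase)
}

#' Maximum unambiguous range for a config
#'
#' The beat frequency 2*K*R/c of a reflector at range R must stay below the
#' complex-sampling limit Fs/2 used by the range FFT.
#' @param config A [radar_config()].
#' @return Range (m).
#' @export
max_unambiguous_range <- function(config) {
  C_LIGHT * config$Fs / (4 * config$slope)
}

#' Simulate an FMCW radar I/Q cube
#'
#' Generates the beat signal of a single subject at standoff `R0` whose chest
#' displacement phase-modulates the slow-time signal:
#' \deqn{I(t) + jQ(t) = A_r \exp\{j[4\pi(R_0 + x(nT_s))/\lambda + 2\pi K \tau t]\}}
#' with \eqn{\tau = 2R_0/c}, evaluated per frame `n` on the fast-time grid,
#' plus static clutter beat tones, DC offsets, per-frame phase noise
#' (independent on I and Q), white noise, and impulse-corrupted frames.
#' The realisation is fully determined by `imp$seed`.
#'
#' @param config A [radar_config()].
#' @param motion A [chest_motion()].
#' @param imp An [impairment_model()].
#' @param amplitude Beat-signal amplitude of the subject's reflection.
#' @return An [iq_cube()] carrying `motion` as ground truth; the slow-time
#'   frame indices hit by impulses are attached as attribute
#'   `impulse_frames` of the `data` matrix's wrapper (`cube$impulse_frames`).
#' @examples
#' cube <- simulate_cube(radar_config(n_frames = 64L), chest_motion(),
#'                       impairment_model(seed = 7))
#' @export
simulate_cube <- function(config, motion, imp = impairment_model(),
                          amplitude = 1) {
  stopifnot(inherits(config, "radar_config"), inherits(motion, "chest_motion"),
            inherits(imp, "impairment_model"))
  rmax <- max_unambiguous_range(config)
  if (motion$R0 >= rmax) {
    stop(sprintf("R0 = %.3g m is beyond the maximum unambiguous range %.3g m for Fs = %.3g Msps",
                 motion$R0, rmax, config$Fs / 1e6))
  }
  for (cl in imp$clutter) {
    if (cl[1] >= rmax) {
      stop(sprintf("clutter at %.3g m is beyond the maximum unambiguous range %.3g m",
                   cl[1], rmax))
    }
  }
  n_s <- config$n_samples
  n_f <- config$n_frames
  t_fast <- (0:(n_s - 1)) / config$Fs
  t_slow <- (0:(n_f - 1)) * config$Ts
  lam <- config$lambda_max
  x <- chest_displacement(motion, t_slow)

  withr::with_seed(imp$seed, {
    # beat tone of the subject: fast-time frequency set by R0, slow-time phase by x(t)
    fb <- 2 * config$slope * motion$R0 / C_LIGHT
    psi <- 4 * pi * (motion$R0 + x) / lam
    dphi_i <- if (imp$phase_noise_std > 0) rnorm(n_f, 0, imp$phase_noise_std) else numeric(n_f)
    dphi_q <- if (imp$phase_noise_std > 0) rnorm(n_f, 0, imp$phase_noise_std) else numeric(n_f)
    fast_arg <- 2 * pi * fb * t_fast
    I <- amplitude * cos(outer(fast_arg, psi + dphi_i, `+`))
    Q <- amplitude * sin(outer(fast_arg, psi + dphi_q, `+`))

    # static clutter reflectors: pure beat tones, no slow-time variation
    for (cl in imp$clutter) {
      arg <- 2 * pi * (2 * config$slope * cl[1] / C_LIGHT) * t_fast +
        4 * pi * cl[1] / lam
      I <- I + cl[2] * cos(arg)
      Q <- Q + cl[2] * sin(arg)
    }

    I <- I + imp$dc_i
    Q <- Q + imp$dc_q
    if (imp$awgn_std > 0) {
      I <- I + matrix(rnorm(n_s * n_f, 0, imp$awgn_std), n_s, n_f)
      Q <- Q + matrix(rnorm(n_s * n_f, 0, imp$awgn_std), n_s, n_f)
    }

    # impulse artifacts: broadband interference bursts hitting whole frames
    # (white across fast time, so every range bin sees them)
    impulse_frames <- integer(0)
    n_imp <- round(imp$impulse_rate * n_f)
    if (n_imp > 0 && imp$impulse_amp > 0) {
      impulse_frames <- sort(sample.int(n_f, min(n_imp, n_f)))
      for (fr in impulse_frames) {
        I[, fr] <- I[, fr] + rnorm(n_s, 0, imp$impulse_amp)
        Q[, fr] <- Q[, fr] + rnorm(n_s, 0, imp$impulse_amp)
      }
    }

    cube <- iq_cube(matrix(complex(real = I, imaginary = Q), n_s, n_f),
                    config, truth = motion)
    cube$impulse_frames <- impulse_frames
    cube
  })
}

#' Inject isolated impulse artifacts into a series
#'
#' Adds `round(impulse_rate * length)` spikes of amplitude `impulse_amp`
#' (random sign) at seeded positions; used to emulate the impulse noise that
#' phase differencing produces, with known ground-truth positions.
#'
#' @param series Numeric series.
#' @param imp An [impairment_model()] providing `impulse_rate`, `impulse_amp`
#'   and `seed`.
#' @return List with `values` (corrupted series) and `positions` (indices hit).
#' @export
inject_impulses <- function(series, imp) {
  stopifnot(inherits(imp, "impairment_model"))
  n <- length(series)
  n_imp <- round(imp$impulse_rate * n)
  if (n_imp == 0 || imp$impulse_amp == 0) {
    return(list(values = series, positions = integer(0)))
  }
  withr::with_seed(imp$seed, {
    pos <- sort(sample.int(n, min(n_imp, n)))
    sgn <- sample(c(-1, 1), length(pos), replace = TRUE)
    out <- series
    out[pos] <- out[pos] + sgn * imp$impulse_amp
    list(values = out, positions = pos)
  })
}
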