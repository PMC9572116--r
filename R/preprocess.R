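#' Range FFT of a radar cube
#'
#' Applies a fast-time window and column-wise FFT to every chirp, turning the
#' raw cube into a range (bin) x slow-time matrix. Range per bin follows from
#' the beat-frequency relation `R = f_b c / (2K)` with `f_b = bin * Fs/n_fft`,
#' i.e. the range resolution is set by the effective sampled bandwidth
#' `slope * n_samples / Fs`.
#'
#' @param cube An [iq_cube()].
#' @param n_fft FFT length, at least `n_samples` (default: `n_samples`, no
#'   zero-padding).
#' @param window `"hann"` (default, for sidelobe control) or `"rectangular"`.
#' @return An object of class `range_profile` with fields `data` (complex
#'   `n_fft x n_frames`), `bin_to_range` (m; 0-based bin `i` maps to element
#'   `i+1`), `config`, `window`, `n_fft`.
#' @export
range_fft <- function(cube, n_fft = NULL, window = c("hann", "rectangular")) {
  stopifnot(inherits(cube, "iq_cube"))
  window <- match.arg(window)
  n_s <- cube$config$n_samples
  n_fft <- as.integer(n_fft %||% n_s)
  if (n_fft < n_s) stop("n_fft must be at least n_samples")
  w <- switch(window,
    hann = 0.5 - 0.5 * cos(2 * pi * (0:(n_s - 1)) / (n_s - 1)),
    rectangular = rep(1, n_s)
  )
  x <- cube$data * w
  if (n_fft > n_s) {
    x <- rbind(x, matrix(0 + 0i, n_fft - n_s, ncol(x)))
  }
  sp <- mvfft(x)
  bin_to_range <- (0:(n_fft - 1)) * cube$config$Fs / n_fft *
    C_LIGHT / (2 * cube$config$slope)
  structure(list(data = sp, bin_to_range = bin_to_range,
                 config = cube$config, window = window, n_fft = n_fft),
            class = "range_profile")
}

#' Remove static clutter by slow-time mean subtraction
#'
#' Subtracts the slow-time mean of every range bin, cancelling reflections
#' from stationary objects while retaining the subject's motion-modulated
#' signal. The output's slow-time mean is zero per bin, and adding the
#' removed means back reconstructs the input exactly.
#'
#' @param rp A `range_profile` from [range_fft()].
#' @return A `range_profile` with the per-bin means removed; the removed means
#'   are stored in field `removed_mean`.
#' @export
remove_static_clutter <- function(rp) {
  stopifnot(inherits(rp, "range_profile"))
  if (ncol(rp$data) < 2) stop("clutter removal needs at least 2 frames")
  mu <- rowMeans(rp$data)
  rp$data <- rp$data - mu
  rp$removed_mean <- mu
  rp
}

#' Select the target range bin
#'
#' After clutter removal the subject's bin is the one whose slow-time series
#' still varies: the bin maximising the slow-time variance of the complex
#' magnitude is selected, ties broken to the lowest index.
#'
#' @param rp A clutter-removed `range_profile`.
#' @return An object of class `range_bin_selection`: `bin_index` (0-based),
#'   `range_m`, `slow_time` (the selected complex series) and
#'   `selection_score` (the winning variance).
#' @export
select_range_bin <- function(rp) {
  stopifnot(inherits(rp, "range_profile"))
  mag <- abs(rp$data)
  if (all(mag == 0)) stop("all-zero range profile: no target to select")
  score <- apply(mag, 1, var)
  bin <- which.max(score) # which.max returns the first (lowest-index) maximum
  structure(list(
    bin_index = bin - 1L,
    range_m = rp$bin_to_range[bin],
    slow_time = rp$data[bin, ],
    selection_score = score[bin]
  ), class = "range_bin_selection")
}
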