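# Symlet-4 quadrature mirror filter pair (orthonormal, sum(lo) = sqrt(2)).
SYM4_DEC_LO <- c(-0.07576571478927333, -0.02963552764599851,
                  0.49761866763201545,  0.80373875180591614,
                  0.29785779560527736, -0.09921954357684722,
                 -0.01260396726203783,  0.03222310060404270)
SYM4_DEC_HI <- rev(SYM4_DEC_LO) * c(1, -1, 1, -1, 1, -1, 1, -1)

# circular filtering with the level-j upsampled MODWT filter (dilation 2^(j-1))
modwt_filter <- function(v, filt, j) {
  n <- length(v)
  out <- numeric(n)
  step <- 2^(j - 1)
  t0 <- 0:(n - 1)
  for (l in seq_along(filt)) {
    shift <- ((l - 1) * step) %% n
    out <- out + filt[l] * v[((t0 - shift) %% n) + 1]
  }
  out
}

modwt_unfilter <- function(w, filt, j) {
  n <- length(w)
  out <- numeric(n)
  step <- 2^(j - 1)
  t0 <- 0:(n - 1)
  for (l in seq_along(filt)) {
    shift <- ((l - 1) * step) %% n
    out <- out + filt[l] * w[((t0 + shift) %% n) + 1]
  }
  out
}

# Maximal-overlap DWT: shift-invariant, defined for any length, and exactly
# invertible, which keeps the denoised + residual = input identity exact.
modwt_sym4 <- function(x, levels) {
  h <- SYM4_DEC_HI / sqrt(2)
  g <- SYM4_DEC_LO / sqrt(2)
  v <- x
  W <- vector("list", levels)
  for (j in seq_len(levels)) {
    W[[j]] <- modwt_filter(v, h, j)
    v <- modwt_filter(v, g, j)
  }
  list(details = W, smooth = v)
}

imodwt_sym4 <- function(dec) {
  h <- SYM4_DEC_HI / sqrt(2)
  g <- SYM4_DEC_LO / sqrt(2)
  levels <- length(dec$details)
  v <- dec$smooth
  for (j in rev(seq_len(levels))) {
    v <- modwt_unfilter(dec$details[[j]], h, j) + modwt_unfilter(v, g, j)
  }
  v
}

#' Soft-threshold a value
#'
#' `sgn(x) (|x| - T)` when `|x| > T`, else 0. Vectorised over `x`.
#'
#' @param x Numeric value(s).
#' @param T Non-negative threshold.
#' @return Thresholded value(s).
#' @export
soft_threshold <- function(x, T) {
  if (T < 0) stop("threshold must be non-negative")
  sign(x) * pmax(abs(x) - T, 0)
}

#' Wavelet-threshold denoising of the noise-reference IMF
#'
#' Denoises the first (noise-dominated) VMD mode with a 4-level sym4 wavelet
#' decomposition and universal soft thresholding: all detail coefficients are
#' shrunk by `T = sigma * sqrt(2 log N)` with the noise scale
#' `sigma = median(|finest details|) / 0.6745`. A shift-invariant
#' (maximal-overlap) transform is used so the decomposition is defined for
#' any signal length and reconstruction is exact.
#'
#' @param imf1 Numeric series, length >= `2^levels`.
#' @param params A [wit_params()] supplying `levels`.
#' @return List with `denoised` and `noise_residual` (`imf1 - denoised`).
#' @export
wavelet_denoise_imf1 <- function(imf1, params = wit_params()) {
  levels <- params$levels
  n <- length(imf1)
  if (n < 2^levels) {
    stop(sprintf("input length %d is shorter than 2^levels = %d", n, 2^levels))
  }
  dec <- modwt_sym4(imf1, levels)
  sigma <- median(abs(dec$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n))
  dec$details <- lapply(dec$details, soft_threshold, T = thr)
  den <- imodwt_sym4(dec)
  list(denoised = den, noise_residual = imf1 - den)
}
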