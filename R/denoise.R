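#' Wavelet-interval-thresholding parameters
#'
#' Constants of the iterative impulse denoiser: the interval-threshold scale
#' `C`, the noise-energy decay model parameters `beta` and `rho` (the noise
#' energy of mode i is `E1 / (beta * rho^i)` for i >= 2), the number of
#' averaging iterations `A`, the wavelet settings, and the candidate range of
#' VMD mode counts scanned by [select_K()].
#'
#' Defaults follow the denoiser's reference operating point: `C = 0.025`,
#' `beta = 0.719`, `rho = 2.01`, `A = 30`, sym4 wavelet with 4 decomposition
#' levels, mode counts 2..8.
#'
#' @param C Threshold constant.
#' @param beta,rho Noise-energy decay parameters.
#' @param A Number of shift-and-threshold iterations averaged.
#' @param wavelet Wavelet basis name (only `"sym4"` is implemented).
#' @param levels Wavelet decomposition depth.
#' @param k_range Candidate VMD mode counts (minimum 2).
#' @param noise_mode Which end of the centre-frequency ordering is the
#'   noise-reference IMF. With vital signs below ~3.3 Hz, broadband noise
#'   concentrates in the `"highest"`-frequency mode (default).
#' @param seed Master seed for the random circular shifts.
#' @return Object of class `wit_params`.
#' @export
wit_params <- function(C = 0.025, beta = 0.719, rho = 2.01, A = 30L,
                       wavelet = "sym4", levels = 4L, k_range = 2:8,
                       noise_mode = c("highest", "lowest"), seed = 1L) {
  if (A < 1) stop("A must be at least 1")
  if (length(k_range) == 0 || min(k_range) < 2) {
    stop("k_range must be non-empty with minimum at least 2")
  }
  if (!identical(wavelet, "sym4")) stop("only the sym4 wavelet is implemented")
  structure(list(C = C, beta = beta, rho = rho, A = as.integer(A),
                 wavelet = wavelet, levels = as.integer(levels),
                 k_range = as.integer(k_range),
                 noise_mode = match.arg(noise_mode),
                 seed = as.integer(seed)),
            class = "wit_params")
}

# index of the noise-reference IMF in a centre-frequency-sorted imf_set
noise_mode_index <- function(dec, noise_mode) {
  if (noise_mode == "highest") which.max(dec$center_freqs) else which.min(dec$center_freqs)
}

# lag-1 normalized cross-correlation between the noise-reference mode and the
# reconstructed remainder: rho_c = R_{1,h}(1) / sqrt(R_{1,1}(0) R_{h,h}(0)).
cross_corr_lag1 <- function(x1, xh) {
  n <- length(x1)
  den <- sqrt(sum(x1^2) * sum(xh^2))
  if (den == 0) return(0)
  sum(x1[2:n] * xh[1:(n - 1)]) / den
}

#' Select the VMD mode count by minimal noise/signal cross-correlation
#'
#' For each candidate K the signal is decomposed, the noise-reference mode is
#' split from the reconstructed remainder, and the magnitude of their lag-1
#' normalized cross-correlation is computed; the K with the smallest value
#' (tie: smaller K) is returned. A well-chosen K leaves the noise mode least
#' correlated with the retained signal.
#'
#' @param x Signal.
#' @param params A [wit_params()] (supplies `k_range` and `noise_mode`).
#' @param vparams A [vmd_params()] (its `K` is overridden per candidate).
#' @return Integer K from `k_range`.
#' @export
select_K <- function(x, params = wit_params(), vparams = vmd_params()) {
  scores <- vapply(params$k_range, function(K) {
    dec <- suppressWarnings(vmd(x, vparams, K = K))
    i1 <- noise_mode_index(dec, params$noise_mode)
    abs(cross_corr_lag1(dec$modes[, i1],
                        rowSums(dec$modes[, -i1, drop = FALSE])))
  }, numeric(1))
  params$k_range[which.min(scores)]
}

#' Interval (between-zero-crossing) thresholding of an IMF
#'
#' Partitions the series into units bounded by consecutive zero crossings and
#' applies a hard decision per unit: a unit whose extremum magnitude exceeds
#' `Ti` is shrunk by the factor `(|extremum| - Ti) / |extremum|`, otherwise
#' the whole unit is zeroed. Boundary segments are ordinary units.
#'
#' @param imf Numeric series.
#' @param Ti Non-negative threshold.
#' @return Thresholded series, same length.
#' @export
interval_threshold <- function(imf, Ti) {
  if (Ti < 0) stop("threshold must be non-negative")
  n <- length(imf)
  s <- ifelse(imf >= 0, 1, -1)
  unit_id <- cumsum(c(1L, as.integer(s[-1] != s[-n])))
  out <- imf
  for (u in split(seq_len(n), unit_id)) {
    m <- max(abs(imf[u]))
    out[u] <- if (m > Ti) imf[u] * (m - Ti) / m else 0
  }
  out
}

#' Per-mode interval threshold from the noise-energy decay model
#'
#' The noise-only energy of mode i is `E1` for i = 1 (the noise-reference
#' mode) and `E1 / (beta * rho^i)` for i >= 2; the interval threshold is
#' `Ti = C * sqrt(2 * Ei * log(N))`.
#'
#' @param E1 Energy (sum of squares) of the noise-reference IMF; must be > 0.
#' @param i Mode index (1 = noise-reference).
#' @param N Length of the IMF (>= 2).
#' @param params A [wit_params()] supplying `C`, `beta`, `rho`.
#' @return Threshold Ti.
#' @export
noise_threshold <- function(E1, i, N, params = wit_params()) {
  if (N < 2) stop("N must be at least 2 (log N must be positive)")
  if (E1 <= 0) stop("E1 must be positive")
  if (i < 1) stop("mode index must be >= 1")
  Ei <- if (i == 1) E1 else E1 / (params$beta * params$rho^i)
  params$C * sqrt(2 * Ei * log(N))
}

#' Random circular shift
#'
#' Cyclically rotates a series by a uniformly drawn offset in `[0, N)`; the
#' multiset of values (hence the energy) is preserved exactly.
#'
#' @param x Numeric series.
#' @param offset Integer shift; drawn uniformly when `NULL`.
#' @return Shifted series.
#' @export
random_circular_shift <- function(x, offset = NULL) {
  n <- length(x)
  if (is.null(offset)) offset <- sample.int(n, 1) - 1L
  offset <- offset %% n
  if (offset == 0) return(x)
  c(x[(n - offset + 1):n], x[1:(n - offset)])
}

#' Iterative VMD wavelet-interval-thresholding impulse denoiser
#'
#' Removes impulse noise from a (phase-difference) series by the following
#' loop. First the signal is decomposed with VMD at a mode count `K1` chosen
#' by [select_K()]; the noise-reference mode is wavelet-denoised
#' ([wavelet_denoise_imf1()]) and its filtered-out part becomes the noise
#' component, while the denoised part plus the remaining modes form the
#' signal component `yr`. Then, `A` times: the noise component is randomly
#' circularly shifted and added back to `yr`; the surrogate is re-decomposed
#' with VMD (`K2` re-selected each iteration); every mode is
#' interval-thresholded with the [noise_threshold()] of its rank (modes
#' ordered from the noise-reference end); and the thresholded modes are
#' summed. The `A` single-iteration reconstructions are averaged — the
#' randomly shifted noise realisations offset each other in the mean while
#' the coherent signal does not.
#'
#' @param x Numeric series (the impulse-corrupted phase-difference signal).
#' @param wit A [wit_params()] (supplies `A`, thresholds and the master seed).
#' @param vparams A [vmd_params()].
#' @return Denoised series, same length as `x`, with attribute `diagnostics`:
#'   a list with `K1`, per-iteration `K2`, per-iteration thresholds, and the
#'   count of VMD runs that hit the iteration cap (`n_unconverged`).
#' @export
ivmd_wit <- function(x, wit = wit_params(), vparams = vmd_params()) {
  n <- length(x)
  n_unconverged <- 0L
  count_vmd <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("VMD did not meet tolerance", conditionMessage(w))) {
        n_unconverged <<- n_unconverged + 1L
        invokeRestart("muffleWarning")
      }
    })
  }

  K1 <- count_vmd(select_K(x, wit, vparams))
  dec1 <- count_vmd(vmd(x, vparams, K = K1))
  i1 <- noise_mode_index(dec1, wit$noise_mode)
  imf11 <- dec1$modes[, i1]
  # remainder includes the VMD residual so that imf11 + remainder = x exactly
  remainder <- x - imf11
  wd <- wavelet_denoise_imf1(imf11, wit)
  yr <- remainder + wd$denoised
  noise <- wd$noise_residual

  offsets <- withr::with_seed(wit$seed, sample.int(n, wit$A, replace = TRUE) - 1L)
  K2 <- integer(wit$A)
  thresholds <- vector("list", wit$A)
  acc <- numeric(n)
  for (a in seq_len(wit$A)) {
    yn <- yr + random_circular_shift(noise, offsets[a])
    K2[a] <- count_vmd(select_K(yn, wit, vparams))
    dec2 <- count_vmd(vmd(yn, vparams, K = K2[a]))
    # rank modes from the noise-reference end: i = 1 is the noise mode
    ord <- if (wit$noise_mode == "highest") {
      order(dec2$center_freqs, decreasing = TRUE)
    } else {
      order(dec2$center_freqs)
    }
    # noise-only energy of the reference mode: the energy of the noise
    # component injected into this surrogate (invariant under the shift)
    E1 <- sum(noise^2)
    Ti <- vapply(seq_len(K2[a]), function(i) {
      if (E1 > 0) noise_threshold(E1, i, n, wit) else 0
    }, numeric(1))
    yi <- numeric(n)
    for (i in seq_len(K2[a])) {
      yi <- yi + interval_threshold(dec2$modes[, ord[i]], Ti[i])
    }
    thresholds[[a]] <- Ti
    acc <- acc + yi
  }
  out <- acc / wit$A
  attr(out, "diagnostics") <- list(K1 = K1, K2 = K2, thresholds = thresholds,
                                   n_unconverged = n_unconverged,
                                   offsets = offsets)
  out
}
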