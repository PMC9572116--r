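#' Fit a circle to the I/Q constellation by non-linear least squares
#'
#' Estimates the DC offset (circle centre) and radius of the slow-time
#' constellation. A Kasa-style algebraic fit provides the deterministic
#' starting point; Levenberg-Marquardt then minimises the geometric residual
#' \eqn{\sum_i (\|p_i - c\| - r)^2}.
#'
#' @param slow_time Complex slow-time series (at least 3 non-collinear points).
#' @param tol Convergence tolerance on the objective (default 1e-10).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `circle_fit`: `center_i`, `center_q`, `radius`,
#'   `residual` (RMS geometric error).
#' @export
fit_circle_nlls <- function(slow_time, tol = 1e-10, max_iter = 100L) {
  xs <- Re(slow_time); ys <- Im(slow_time)
  if (length(xs) < 3) stop("circle fitting needs at least 3 points")
  # collinearity check on centered coordinates
  M <- cbind(xs - mean(xs), ys - mean(ys))
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[2] < 1e-10 * max(sv[1], 1e-300)) {
    stop("points are collinear or degenerate: circle fit is not identifiable")
  }
  # Kasa algebraic fit: minimise ||x^2+y^2 - 2a x - 2b y - d||
  A <- cbind(2 * xs, 2 * ys, 1)
  rhs <- xs^2 + ys^2
  ab <- qr.solve(A, rhs)
  start <- c(ab[1], ab[2], sqrt(max(ab[3] + ab[1]^2 + ab[2]^2, 1e-300)))
  res_fun <- function(p) sqrt((xs - p[1])^2 + (ys - p[2])^2) - p[3]
  fit <- minpack.lm::nls.lm(
    par = start, fn = res_fun,
    control = minpack.lm::nls.lm.control(ftol = tol, ptol = tol,
                                         maxiter = as.integer(max_iter))
  )
  p <- fit$par
  r <- res_fun(p)
  structure(list(center_i = p[1], center_q = p[2],
                 radius = abs(p[3]),
                 residual = sqrt(mean(r^2))),
            class = "circle_fit")
}

#' Compensate the DC offset of a slow-time series
#'
#' Subtracts the fitted constellation centre so the arc sits around the
#' origin, which is required for undistorted phase demodulation.
#'
#' @param slow_time Complex series.
#' @param fit A `circle_fit` from [fit_circle_nlls()].
#' @return Complex series with the centre removed.
#' @export
compensate_dc <- function(slow_time, fit) {
  stopifnot(inherits(fit, "circle_fit"))
  slow_time - complex(real = fit$center_i, imaginary = fit$center_q)
}

#' Phase series container
#'
#' @param values Numeric values (rad, rad/frame, or m depending on `kind`).
#' @param fs_slow Slow-time sampling rate (Hz).
#' @param kind One of `"phase"`, `"phase_diff"`, `"displacement"`.
#' @return Object of class `phase_series`.
#' @export
phase_series <- function(values, fs_slow, kind = c("phase", "phase_diff", "displacement")) {
  kind <- match.arg(kind)
  if (!all(is.finite(values))) stop("phase series contains non-finite values")
  if (fs_slow <= 0) stop("fs_slow must be positive")
  structure(list(values = values, fs_slow = fs_slow, kind = kind),
            class = "phase_series")
}

#' Extended DACM phase demodulation
#'
#' Extracts the continuous phase of a complex series by the extended
#' differentiate-and-cross-multiply recursion
#' \deqn{\Psi(n) = \sum_{i=2}^{n} \frac{I_i(Q_i - Q_{i-1}) - Q_i(I_i - I_{i-1})}{I_i^2 + Q_i^2},}
#' which integrates the instantaneous angular rate and therefore never wraps
#' at +/- pi, unlike the raw arctangent.
#'
#' @param slow_time Complex series with no zero-magnitude samples.
#' @param fs_slow Slow-time sampling rate (Hz).
#' @return A [phase_series()] of kind `"phase"`, first element 0.
#' @export
extract_phase_dacm <- function(slow_time, fs_slow = 20) {
  I <- Re(slow_time); Q <- Im(slow_time)
  mag2 <- I^2 + Q^2
  if (any(mag2 == 0)) {
    stop(sprintf("zero-magnitude sample at index %d: phase undefined",
                 which(mag2 == 0)[1]))
  }
  n <- length(slow_time)
  incr <- (I[-1] * diff(Q) - Q[-1] * diff(I)) / mag2[-1]
  phase_series(c(0, cumsum(incr)), fs_slow, "phase")
}

#' First-order phase difference
#'
#' Forward-differences a phase series, attenuating the large low-frequency
#' breathing component relative to the heartbeat (gain `2 sin(pi f / fs)` at
#' frequency f). Output length is n-1; no boundary sample is invented.
#'
#' @param ps A [phase_series()] of kind `"phase"`.
#' @return A [phase_series()] of kind `"phase_diff"`, length `n - 1`.
#' @export
phase_difference <- function(ps) {
  stopifnot(inherits(ps, "phase_series"))
  if (ps$kind != "phase") stop("phase_difference expects a series of kind 'phase'")
  if (length(ps$values) < 2) stop("phase series too short to difference")
  phase_series(diff(ps$values), ps$fs_slow, "phase_diff")
}
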