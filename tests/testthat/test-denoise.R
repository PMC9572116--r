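test_that("soft threshold follows the piecewise definition", {
  expect_equal(soft_threshold(1, 1), 0)
  expect_equal(soft_threshold(2, 1), 1)
  expect_equal(soft_threshold(-2, 1), -1)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(c(-4, 0, 4), 1.5), c(-2.5, 0, 2.5))
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("wavelet denoising is additive, shrinks white noise, passes zero", {
  zero <- wavelet_denoise_imf1(numeric(64))
  expect_equal(zero$denoised, numeric(64))
  expect_equal(zero$noise_residual, numeric(64))

  withr::with_seed(11, {
    x <- rnorm(255)
  })
  out <- wavelet_denoise_imf1(x)
  expect_equal(out$denoised + out$noise_residual, x, tolerance = 1e-10)

  # with no thresholding the transform itself reconstructs exactly
  dec <- fmcwvitals:::modwt_sym4(x, 4)
  expect_equal(fmcwvitals:::imodwt_sym4(dec), x, tolerance = 1e-10)

  shrink <- sapply(1:20, function(s) {
    withr::with_seed(s, n <- rnorm(1024))
    sum(wavelet_denoise_imf1(n)$denoised^2) < sum(n^2)
  })
  expect_true(all(shrink))

  expect_error(wavelet_denoise_imf1(rnorm(8)), "shorter")
})

test_that("random circular shift permutes values and preserves energy", {
  x <- rnorm(100)
  expect_identical(random_circular_shift(x, 0), x)
  y <- random_circular_shift(x, 37)
  expect_equal(sort(y), sort(x))
  expect_identical(sum(y^2), sum(x^2))
  expect_equal(random_circular_shift(x, 100), x)
  expect_equal(random_circular_shift(x, 137), random_circular_shift(x, 37))
})

test_that("interval thresholding scales or zeroes whole units", {
  t <- (0:199) / 20
  x <- sin(2 * pi * 1 * t) # units are half-periods with extremum 1
  half <- interval_threshold(x, 0.5)
  expect_equal(max(abs(half)), 0.5, tolerance = 1e-6)
  expect_equal(half, x * 0.5, tolerance = 1e-6)

  expect_equal(interval_threshold(x, 2), rep(0, 200))
  expect_equal(interval_threshold(x, 0), x)

  # no new sign changes inside kept units (random signals, fixed seed)
  withr::with_seed(3, {
    for (rep in 1:5) {
      z <- rnorm(120)
      out <- interval_threshold(z, 0.8)
      kept <- out != 0
      expect_true(all(sign(out[kept]) == sign(z[kept])))
    }
  })
})

test_that("noise thresholds decay geometrically across mode ranks", {
  p <- wit_params()
  Ti <- sapply(1:6, function(i) noise_threshold(1, i, 256, p))
  # rank 1 uses the full noise energy; deeper (lower-frequency) ranks decay
  expect_true(all(diff(Ti[-1]) < 0))
  expect_equal(Ti[2], p$C * sqrt(2 * log(256) / (p$beta * p$rho^2)))
  expect_equal(noise_threshold(1, 2, 256, p) / noise_threshold(1, 3, 256, p),
               sqrt(p$rho))
  expect_error(noise_threshold(1, 1, 1, p), "at least 2")
  expect_error(noise_threshold(0, 1, 256, p), "positive")
})

test_that("select_K stays in range, is deterministic, matches a brute-force scan", {
  withr::with_seed(21, {
    x <- two_tone()$x + 0.2 * rnorm(255)
  })
  wit <- wit_params()
  K <- select_K(x, wit)
  expect_true(K %in% 2:8)
  expect_identical(select_K(x, wit), K)

  # independent brute-force evaluation of the lag-1 cross-correlation scan
  brute <- sapply(2:8, function(k) {
    dec <- suppressWarnings(vmd(x, vmd_params(), K = k))
    i1 <- which.max(dec$center_freqs)
    noise <- dec$modes[, i1]
    sig <- rowSums(dec$modes[, -i1, drop = FALSE])
    n <- length(noise)
    abs(sum(noise[-1] * sig[-n]) / sqrt(sum(noise^2) * sum(sig^2)))
  })
  expect_equal(K, (2:8)[which.min(brute)])
})

test_that("ivmd_wit is reproducible, length-preserving and passes clean signals", {
  tt <- two_tone()
  # degenerate single iteration with a fixed master seed is deterministic
  w1 <- wit_params(A = 1L, seed = 9)
  d1 <- ivmd_wit(tt$x, w1)
  d2 <- ivmd_wit(tt$x, w1)
  expect_identical(as.numeric(d1), as.numeric(d2))
  expect_length(as.numeric(d1), 255)
  expect_true(all(is.finite(d1)))

  # clean two-tone input passes through nearly unchanged
  den <- as.numeric(ivmd_wit(tt$x, wit_params(A = 5, seed = 1)))
  expect_gt(cor(den, tt$x), 0.99)

  diag <- attr(d1, "diagnostics")
  expect_true(diag$K1 %in% 2:8)
  expect_length(diag$K2, 1)
})

test_that("denoising raises the spectral SNR of both tones under impulse noise", {
  improved <- sapply(1:10, function(s) {
    tt <- two_tone()
    imp <- impairment_model(impulse_rate = 0.02, impulse_amp = 1.0, seed = s)
    withr::with_seed(s + 1000, wn <- rnorm(255, 0, 0.02))
    noisy <- inject_impulses(tt$x, imp)$values + wn
    den <- as.numeric(ivmd_wit(noisy, wit_params(A = 30, seed = s)))
    c(snr_at_tone(den, 0.3) > snr_at_tone(noisy, 0.3),
      snr_at_tone(den, 1.2) > snr_at_tone(noisy, 1.2))
  })
  expect_true(all(improved))
})

test_that("averaging the shifted reconstructions reduces variance", {
  tt <- two_tone()
  imp <- impairment_model(impulse_rate = 0.02, impulse_amp = 1.0, seed = 5)
  noisy <- inject_impulses(tt$x, imp)$values
  singles <- sapply(1:8, function(a) {
    as.numeric(ivmd_wit(noisy, wit_params(A = 1, seed = a)))
  })
  avg <- rowMeans(singles)
  resid_var_single <- mean(apply(singles - tt$x, 2, var))
  resid_var_avg <- var(avg - tt$x)
  expect_lt(resid_var_avg, resid_var_single)
})
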