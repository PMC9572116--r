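test_that("radar_config derives wavelength and bandwidths, rejects bad timing", {
  cfg <- radar_config()
  expect_equal(cfg$lambda_max, 299792458 / 77e9, tolerance = 1e-9)
  expect_equal(cfg$bandwidth, 4e9)
  expect_equal(cfg$bandwidth_eff, 80e12 * 256 / 6.4e6)
  expect_error(radar_config(fc = -1), "positive")
  # sampling window longer than the chirp is impossible
  expect_error(radar_config(Tc = 30e-6), "exceeds the chirp duration")
})

test_that("chest displacement follows the breathing+heartbeat model", {
  t <- seq(0, 10, by = 0.05)
  zero <- chest_motion(breath_amp = 0, heart_amp = 0, harmonic_coeffs = 0)
  expect_equal(chest_displacement(zero, t), rep(0, length(t)))

  m <- chest_motion(breath_amp = 1e-3, breath_freq = 0.3, heart_amp = 0,
                    harmonic_coeffs = numeric(0))
  expect_equal(chest_displacement(m, 0), 0) # sine convention at the origin
  x <- chest_displacement(m, t)
  expect_equal(max(abs(x)), 1e-3, tolerance = 1e-3)

  full <- chest_motion()
  bound <- full$breath_amp * (1 + sum(full$harmonic_coeffs)) + full$heart_amp
  expect_true(max(abs(chest_displacement(full, t))) <= bound)
  expect_error(chest_displacement(full, numeric(0)), "empty")
  expect_error(chest_displacement(full, c(1, 0.5)), "monotone")
})

test_that("simulate_cube is seed-reproducible and places the beat tone analytically", {
  cube1 <- test_cube(seed = 42)
  cube2 <- test_cube(seed = 42)
  expect_identical(cube1$data, cube2$data)

  # no motion, no noise: slow time is constant at every fast-time index
  cfg <- radar_config(n_frames = 32L)
  still <- chest_motion(breath_amp = 0, heart_amp = 0, harmonic_coeffs = 0)
  cube <- simulate_cube(cfg, still, impairment_model())
  expect_lt(max(abs(cube$data - cube$data[, 1])), 1e-12)

  # beat tone lands at the bin predicted by fb = 2 K R0 / c
  moving <- test_cube(seed = 1, noise = FALSE)
  rp <- remove_static_clutter(range_fft(moving, window = "rectangular"))
  sel <- select_range_bin(rp)
  expect_equal(sel$bin_index, beat_bin(moving$config, 1.0))

  expect_error(
    simulate_cube(radar_config(), chest_motion(R0 = 50), impairment_model()),
    "unambiguous range"
  )
})

test_that("a displacement step of lambda/8 advances the slow-time phase by pi/2", {
  cfg <- radar_config(n_frames = 16L)
  lam <- cfg$lambda_max
  # square-wave-like step via two simulations differing by lambda/8 in R0
  m1 <- chest_motion(R0 = 1.0, breath_amp = 0, heart_amp = 0, harmonic_coeffs = 0)
  m2 <- chest_motion(R0 = 1.0 + lam / 8, breath_amp = 0, heart_amp = 0,
                     harmonic_coeffs = 0)
  c1 <- simulate_cube(cfg, m1, impairment_model())
  c2 <- simulate_cube(cfg, m2, impairment_model())
  bin <- beat_bin(cfg, 1.0) + 1
  p1 <- Arg(range_fft(c1, window = "rectangular")$data[bin, 1])
  p2 <- Arg(range_fft(c2, window = "rectangular")$data[bin, 1])
  dphi <- (p2 - p1) %% (2 * pi)
  # 4 pi (lambda/8) / lambda = pi/2, plus a small beat-frequency migration
  # term 4 pi K dR t / c over the fast-time window (~0.03 rad here)
  expect_equal(dphi, pi / 2, tolerance = 0.05 / (pi / 2))
})

test_that("simulator slow-time phase equals 4 pi x(t)/lambda at the target bin", {
  cfg <- radar_config(n_frames = 128L)
  motion <- chest_motion(R0 = 1.0, breath_amp = 5e-4, breath_freq = 0.3,
                         heart_amp = 0, harmonic_coeffs = 0)
  cube <- simulate_cube(cfg, motion, impairment_model())
  rp <- remove_static_clutter(range_fft(cube))
  sel <- select_range_bin(rp)
  # DC compensation restores the arc centre, then DACM reads the phase
  st <- compensate_dc(sel$slow_time, fit_circle_nlls(sel$slow_time))
  ph <- extract_phase_dacm(st, fs_slow = 20)$values
  t_slow <- (0:127) * cfg$Ts
  expected <- 4 * pi * chest_displacement(motion, t_slow) / cfg$lambda_max
  expected <- expected - expected[1]
  expect_lt(max(abs(ph - expected)), 0.02)
})

test_that("cube energy grows with white-noise level in expectation", {
  e <- sapply(c(0.02, 0.2), function(sig) {
    mean(sapply(1:20, function(s) {
      cfg <- radar_config(n_samples = 64L, n_frames = 16L)
      imp <- impairment_model(awgn_std = sig, seed = s)
      sum(Mod(simulate_cube(cfg, chest_motion(), imp)$data)^2)
    }))
  })
  expect_gt(e[2], e[1])
})

test_that("inject_impulses bookkeeps positions and is seed-sensitive", {
  x <- sin(seq(0, 10, length.out = 200))
  none <- inject_impulses(x, impairment_model(impulse_rate = 0, seed = 1))
  expect_identical(none$values, x)
  expect_length(none$positions, 0)

  imp <- impairment_model(impulse_rate = 0.05, impulse_amp = 2, seed = 3)
  out <- inject_impulses(x, imp)
  changed <- which(out$values != x)
  expect_identical(changed, out$positions)
  expect_length(out$positions, round(0.05 * 200))

  # different seeds give different position sets essentially always
  sets <- sapply(1:100, function(s) {
    paste(inject_impulses(x, impairment_model(impulse_rate = 0.05,
                                              impulse_amp = 2, seed = s))$positions,
          collapse = ",")
  })
  expect_gt(length(unique(sets)), 95)
})
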