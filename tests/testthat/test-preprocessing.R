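test_that("smoothness-prior detrending matches the dense direct solve", {
  set.seed(1)
  for (lambda in c(1, 10, 300)) {
    x <- cumsum(rnorm(40))
    expect_equal(detrend_smoothness_prior(x, lambda),
                 detrend_bruteforce(x, lambda), tolerance = 1e-10)
  }
})

test_that("detrending limit cases: constants, lambda 0, linear ramps", {
  expect_equal(detrend_smoothness_prior(rep(5, 50), 300), numeric(50))
  expect_equal(detrend_smoothness_prior(rnorm(20), 0), numeric(20))
  ramp <- seq(0, 10, length.out = 200)
  out <- detrend_smoothness_prior(ramp, 1e4)
  expect_lt(max(abs(out)), 0.01 * diff(range(ramp)))
})

test_that("detrending is linear in its input", {
  set.seed(2)
  x <- rnorm(60); y <- rnorm(60)
  expect_equal(detrend_smoothness_prior(2 * x + 3 * y, 50),
               2 * detrend_smoothness_prior(x, 50) +
                 3 * detrend_smoothness_prior(y, 50),
               tolerance = 1e-10)
})

test_that("normalization standardizes, is idempotent and affine invariant", {
  x <- c(1, 2, 3)
  z <- normalize_series(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(normalize_series(z), z)
  expect_equal(normalize_series(5 * x + 2), z)
  expect_error(normalize_series(rep(1, 10)), "variance")
})

test_that("moving average: constants, impulses, alternation, edges", {
  expect_equal(moving_average(rep(3, 10), 5), rep(3, 10))
  imp <- c(rep(0, 5), 1, rep(0, 5))
  expect_equal(moving_average(imp, 5)[4:8], rep(1 / 5, 5))
  alt <- rep(c(1, -1), 10)
  expect_equal(abs(moving_average(alt, 5)[3:18]), rep(1 / 5, 16))
  x <- 1:10
  expect_equal(moving_average(x, 5)[1], mean(x[1:3]))  # shrunk edge window
  expect_equal(moving_average(x, 5)[10], mean(x[8:10]))
  expect_error(moving_average(1:10, 4), "odd")
})

test_that("EMD separates tones by time scale, high frequency first", {
  t <- (0:899) / 30
  x <- sin(2 * pi * 1.2 * t) + sin(2 * pi * 0.1 * t)
  modes <- emd(x, 30)
  freqs <- apply(modes$imfs, 2, dominant_freq, fps = 30)
  i_fast <- which.min(abs(freqs - 1.2))
  i_slow <- which.min(abs(freqs - 0.1))
  expect_lt(i_fast, i_slow)
  expect_equal(freqs[i_fast], 1.2, tolerance = 0.05)
  # mode definition: extrema and zero-crossing counts nearly equal
  for (i in seq_len(ncol(modes$imfs))) {
    h <- modes$imfs[, i]
    n_zc <- sum(abs(diff(sign(h))) > 0)
    n_ex <- sum(diff(sign(diff(h))) != 0)
    expect_lte(abs(n_zc - n_ex), 1)
  }
})

test_that("EEMD reconstructs its input within the averaged-noise bound", {
  set.seed(5)
  t <- (0:599) / 30
  x <- sin(2 * pi * 1.2 * t) + 0.5 * sin(2 * pi * 0.2 * t) + 0.1 * rnorm(600)
  cfg <- preproc_config()
  modes <- eemd(x, 30, cfg, seed = 9)
  rec <- rowSums(modes$imfs) + modes$residual
  rel <- sqrt(mean((rec - x)^2)) / sd(x)
  expect_lt(rel, 2 * cfg$eemd_noise_std / sqrt(cfg$eemd_ensembles) + 0.005)
})

test_that("EEMD is deterministic given its seed", {
  x <- sin(2 * pi * 1.2 * (0:299) / 30) + 0.2 * cos((0:299) / 10)
  a <- eemd(x, 30, seed = 11)
  b <- eemd(x, 30, seed = 11)
  expect_identical(a$imfs, b$imfs)
  expect_identical(a$residual, b$residual)
  c <- eemd(x, 30, seed = 12)
  expect_false(identical(a$imfs, c$imfs))
})

test_that("in-band mode selection picks the pulse-band mode", {
  t <- (0:899) / 30
  set.seed(3)
  fake <- structure(list(imfs = cbind(0.01 * rnorm(900),
                                      sin(2 * pi * 1.2 * t),
                                      sin(2 * pi * 0.1 * t)),
                         residual = numeric(900), fps = 30),
                    class = "imf_set")
  sel <- select_imf_by_band(fake)
  expect_equal(sel$index, 2)
  # ties break to the first (lower) index
  tied <- structure(list(imfs = cbind(sin(2 * pi * t), sin(2 * pi * t)),
                         residual = numeric(900), fps = 30),
                    class = "imf_set")
  expect_equal(select_imf_by_band(tied)$index, 1)
  flat <- structure(list(imfs = cbind(numeric(900)), residual = numeric(900),
                         fps = 30), class = "imf_set")
  expect_error(select_imf_by_band(flat), "in-band")
})

test_that("on a drifting noisy pulse the selected mode is an early IMF", {
  # mirrors the published decomposition pattern: the pulse-band mode sits
  # near the top of the IMF stack after smoothing
  sim <- simulate_pulse_trace(pulse_sim_config(duration_s = 30, fps = 30,
                                               drift_amplitude = 2,
                                               noise_sigma = 0.3, seed = 4))
  pre <- preprocess_trace(sim$trace, cfg = preproc_config(), seed = 4)
  expect_lte(pre$imf_index, 3)
  expect_equal(60 * dominant_freq(pre$series, 30), 72, tolerance = 2)
})

test_that("the preprocessing chain is deterministic given one seed", {
  sim <- simulate_pulse_trace(pulse_sim_config(duration_s = 20, fps = 30,
                                               noise_sigma = 0.2, seed = 6))
  a <- preprocess_trace(sim$trace, cfg = preproc_config(), seed = 21)
  b <- preprocess_trace(sim$trace, cfg = preproc_config(), seed = 21)
  expect_identical(a$series, b$series)
})
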