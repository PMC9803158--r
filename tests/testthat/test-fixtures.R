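test_that("noiseless pulse trace oscillates at the configured rate", {
  sim <- simulate_pulse_trace(pulse_sim_config(duration_s = 60, fps = 30,
                                               hr_bpm = 72, seed = 1))
  expect_length(sim$trace$values, 60 * 30)
  expect_equal(dominant_freq(sim$trace$values, 30), 1.2, tolerance = 0.01)
  expect_equal(sim$hr_bpm, rep(72, 1800))
})

test_that("a piecewise-linear heart-rate schedule is followed window by window", {
  sched <- data.frame(time_s = c(0, 120), hr_bpm = c(66, 84))
  sim <- simulate_pulse_trace(pulse_sim_config(duration_s = 120, fps = 30,
                                               hr_bpm = sched, seed = 3))
  win <- 30 * 30
  for (start in c(1, 1201, 2401)) {
    seg <- sim$trace$values[start:(start + win - 1)]
    hr_true <- mean(sim$hr_bpm[start:(start + win - 1)])
    # a linear chirp's spectral peak sits within the swept band
    expect_lt(abs(60 * dominant_freq(seg, 30) - hr_true), 3)
  }
})

test_that("generators are bitwise deterministic in their seed", {
  cfg <- pulse_sim_config(duration_s = 30, fps = 30, artifact_rate = 6,
                          noise_sigma = 0.3, drift_amplitude = 2, seed = 7)
  expect_identical(simulate_pulse_trace(cfg)$trace$values,
                   simulate_pulse_trace(cfg)$trace$values)
  lcfg <- lowrank_sim_config(40, 50, 3, 0.05, seed = 7)
  expect_identical(simulate_lowrank_sparse(lcfg)$X,
                   simulate_lowrank_sparse(lcfg)$X)
  cfg2 <- pulse_sim_config(duration_s = 30, fps = 30, artifact_rate = 6,
                           noise_sigma = 0.3, drift_amplitude = 2, seed = 8)
  expect_false(identical(simulate_pulse_trace(cfg)$trace$values,
                         simulate_pulse_trace(cfg2)$trace$values))
})

test_that("smoothness-prior detrending removes the simulated drift", {
  sim <- simulate_pulse_trace(pulse_sim_config(duration_s = 60, fps = 30,
                                               drift_amplitude = 3,
                                               drift_period_s = 25, seed = 2))
  x <- sim$trace$values
  y <- detrend_smoothness_prior(x, 300)
  expect_gt(band_power(x, 30, 0.01, 0.2) / band_power(y, 30, 0.01, 0.2), 10)
})

test_that("pulse config rejects out-of-band and malformed settings", {
  expect_error(pulse_sim_config(hr_bpm = 30), "42")
  expect_error(pulse_sim_config(hr_bpm = 200), "hr_bpm")
  expect_error(pulse_sim_config(duration_s = -1), "duration_s")
  expect_error(pulse_sim_config(noise_sigma = -0.1), "noise_sigma")
  sched <- data.frame(time_s = c(0, 10), hr_bpm = c(72, 190))
  expect_error(pulse_sim_config(hr_bpm = sched), "42")
})

test_that("low-rank + sparse generator satisfies its construction contract", {
  sim <- simulate_lowrank_sparse(lowrank_sim_config(100, 120, 5, 0.05,
                                                    seed = 1))
  expect_identical(sim$X, sim$A_true + sim$E_true)
  sv <- svd(sim$A_true)$d
  expect_equal(sum(sv > sv[1] * 120 * .Machine$double.eps), 5)
  expect_equal(sum(sim$E_true != 0), round(0.05 * 100 * 120))
  z <- simulate_lowrank_sparse(lowrank_sim_config(5, 6, 0, 0, seed = 1))
  expect_equal(z$X, matrix(0, 5, 6))
  expect_error(lowrank_sim_config(10, 12, 10, 0.05), "rank")
  expect_error(lowrank_sim_config(10, 12, 2, 0.6), "sparse_fraction")
})

test_that("synthetic skin image colors the rectangle and nothing else", {
  img <- synth_skin_image(20, 10, c(3, 5, 8, 15), c(200, 120, 90),
                          c(0, 0, 255))
  expect_equal(dim(img), c(10, 20, 3))
  expect_true(all(img[3:8, 5:15, 1] == 200))
  expect_true(all(img[1:2, , 3] == 255))
  m <- skin_mask(img)
  inside <- matrix(FALSE, 10, 20); inside[3:8, 5:15] <- TRUE
  expect_identical(m, inside)  # all skin pixels pass, no background does
  dark <- synth_skin_image(20, 10, c(3, 5, 8, 15), c(50, 50, 50))
  expect_false(any(skin_mask(dark)))
  expect_error(synth_skin_image(20, 10, c(3, 5, 8, 25), c(1, 2, 3)),
               "bounds")
})
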