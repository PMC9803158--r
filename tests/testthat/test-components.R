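test_that("autocorrelation matches the double-loop definition", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    z <- rnorm(n)
    max_lag <- sample.int(n - 1, 1)
    expect_lt(max(abs(autocorrelation(z, max_lag) -
                        acf_bruteforce(z, max_lag))), 1e-12)
  }
})

test_that("the zero-lag coefficient is exactly one", {
  set.seed(14)
  for (rep in 1:5) {
    z <- rnorm(50)
    expect_identical(autocorrelation(z, 10)[1], 1)
  }
  expect_error(autocorrelation(rep(2, 30), 5), "variance")
})

test_that("autocorrelation is invariant to scale and sign of the series", {
  set.seed(15)
  z <- rnorm(100)
  P <- autocorrelation(z, 40)
  expect_equal(autocorrelation(5 * z, 40), P, tolerance = 1e-12)
  expect_equal(autocorrelation(-z, 40), P, tolerance = 1e-12)
})

test_that("a sinusoid's autocorrelation peaks near its period", {
  z <- sin(2 * pi * (0:899) / 30)  # period 30 lags, N = 30 periods
  P <- autocorrelation(z, 360)
  expect_gt(P[31], P[30])  # local maximum at lag 30
  expect_gt(P[31], P[32])
  expect_gte(P[31], 0.95)
  rho <- max_autocorr_coefficient(P, select_config(), fps = 30)
  # the largest interior peak is the lag-30 one (within one lag)
  expect_equal(rho, max(P[30:32]), tolerance = 1e-12)
})

test_that("white noise never shows a strong interior peak", {
  for (s in 1:5) {
    set.seed(100 + s)
    P <- autocorrelation(rnorm(1000), 360)
    rho <- max_autocorr_coefficient(P, select_config(), fps = 30)
    expect_lt(rho, 0.2)
  }
})

test_that("peakless autocorrelations score the sentinel -1", {
  P <- exp(-(0:100) / 30)  # monotone decay, no interior peak
  expect_equal(max_autocorr_coefficient(P), -1)
})

test_that("periodic components outscore noise components", {
  set.seed(16)
  tone <- sin(2 * pi * 1.2 * (0:599) / 30)
  noise <- rnorm(600)
  cfg <- select_config()
  r_tone <- max_autocorr_coefficient(autocorrelation(tone, 360), cfg, 30)
  r_noise <- max_autocorr_coefficient(autocorrelation(noise, 360), cfg, 30)
  expect_gt(r_tone, 0.85)
  expect_gt(r_tone, r_noise)
})

test_that("selection keeps the periodic pair and drops broadband noise", {
  set.seed(17)
  t <- (0:899) / 30
  x <- sin(2 * pi * 1.2 * t) + 0.3 * rnorm(900)
  dec <- ssa_decompose(build_trajectory(x, 90))
  sc <- select_components(dec, 10, select_config(), fps = 30)
  expect_true(all(sc$table$selected[1:2]))   # the tone pair
  expect_false(all(sc$table$selected[3:10])) # some noise component fails
  expect_equal(sum(sc$table$weight), 1)
  expect_false(sc$fallback)
})

test_that("a pure sinusoid selects exactly its leading pair", {
  x <- sin(2 * pi * 1.2 * (0:899) / 30)
  dec <- ssa_decompose(build_trajectory(x, 90))
  sc <- select_components(dec, min(6, dec$d), select_config(), fps = 30)
  expect_identical(which(sc$table$selected), 1:2)
  rec <- reconstruct_components(sc)
  # equal singular values: reconstruction is (z1 + z2)/2, i.e. x/2
  expect_gt(cor(rec, x), 0.999)
  expect_equal(rec, x / 2, tolerance = 0.05)
})

test_that("raising the threshold never enlarges the selected set", {
  set.seed(18)
  t <- (0:599) / 30
  x <- sin(2 * pi * 1.2 * t) + 0.5 * sin(2 * pi * 0.25 * t) + 0.4 * rnorm(600)
  dec <- ssa_decompose(build_trajectory(x, 60))
  sel <- lapply(c(0.5, 0.7, 0.85, 0.95), function(th) {
    sc <- select_components(dec, 12, select_config(rho_threshold = th), 30)
    if (sc$fallback) integer(0) else which(sc$table$selected)
  })
  for (i in 1:3) expect_true(all(sel[[i + 1]] %in% sel[[i]]))
})

test_that("empty selections fall back to the best-scoring component", {
  set.seed(19)
  dec <- ssa_decompose(build_trajectory(rnorm(300), 30))
  sc <- select_components(dec, 8, select_config(rho_threshold = 0.99),
                          fps = 30)
  expect_true(sc$fallback)
  expect_equal(sum(sc$table$selected), 1)
  expect_equal(which(sc$table$selected), which.max(sc$table$rho))
  expect_equal(sc$table$weight[sc$table$selected], 1)
})

test_that("reconstruction weighting follows the singular value proportions", {
  z <- cbind(sin(1:100), cos(1:100))
  mk <- function(lambda, denom = "selected") {
    structure(list(table = data.frame(index = 1:2, lambda = lambda,
                                      rho = c(0.9, 0.9),
                                      selected = c(TRUE, TRUE),
                                      weight = lambda / sum(lambda)),
                   series = z, fallback = FALSE),
              class = "component_scores")
  }
  expect_equal(reconstruct_components(mk(c(2, 2))), (z[, 1] + z[, 2]) / 2)
  expect_equal(reconstruct_components(mk(c(3, 1))),
               0.75 * z[, 1] + 0.25 * z[, 2])
  single <- mk(c(2, 2))
  single$table$selected <- c(TRUE, FALSE)
  single$table$weight <- c(1, 0)
  expect_equal(reconstruct_components(single), z[, 1])
})
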