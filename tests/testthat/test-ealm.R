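test_that("soft threshold shrinks toward zero with a dead zone", {
  expect_equal(soft_threshold(1.2, 0.5), 0.7)
  expect_equal(soft_threshold(-1, 2), 0)
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(soft_threshold(x, 0), x)
  expect_equal(soft_threshold(c(-3, 3), 1), c(-2, 2))
  expect_error(soft_threshold(1, -0.1), "tau")
})

test_that("singular value threshold shrinks the spectrum", {
  M <- diag(c(3, 1))
  expect_equal(sv_threshold(M, 2), diag(c(1, 0)), tolerance = 1e-12)
  X <- matrix(rnorm(20), 4, 5)
  expect_equal(sv_threshold(X, 0), X, tolerance = 1e-10)
  expect_equal(sv_threshold(X, svd(X)$d[1] + 1), matrix(0, 4, 5))
})

test_that("initial multiplier follows the sign-matrix normalization", {
  X <- matrix(1, 4, 6)
  eta <- 0.1  # 1/eta = 10 dominates the spectral norm sqrt(24)
  expect_equal(initial_multiplier(X, eta), X / 10)
  eta2 <- 1   # spectral norm sqrt(24) dominates
  expect_equal(initial_multiplier(X, eta2), X / sqrt(24))
  expect_equal(initial_multiplier(matrix(5), 1), matrix(1))
  Y <- matrix(rnorm(24), 4, 6)
  expect_equal(initial_multiplier(3 * Y, 0.2), initial_multiplier(Y, 0.2))
  expect_error(initial_multiplier(matrix(0, 2, 2), 1), "nonzero")
})

test_that("an exactly low-rank matrix splits with a vanishing sparse part", {
  sim <- simulate_lowrank_sparse(lowrank_sim_config(60, 80, 5, 0, seed = 3))
  sp <- ealm_decompose(sim$X)
  expect_equal(sp$s, 5)
  expect_lt(norm(sp$E, "F") / norm(sim$X, "F"), 1e-4)
})

test_that("rank-5 matrices under 5% sparse corruption are recovered", {
  sim <- simulate_lowrank_sparse(lowrank_sim_config(100, 120, 5, 0.05,
                                                    seed = 1))
  sp <- ealm_decompose(sim$X)
  expect_true(sp$converged)
  expect_equal(sp$s, 5)
  expect_lt(norm(sp$A - sim$A_true, "F") / norm(sim$A_true, "F"), 1e-3)
  expect_lte(sp$final_residual, ealm_config()$tol)
})

test_that("the augmented Lagrangian is non-increasing within each inner block", {
  sim <- simulate_lowrank_sparse(lowrank_sim_config(40, 50, 3, 0.05,
                                                    seed = 4))
  sp <- ealm_decompose(sim$X, diagnostics = TRUE)
  lag <- sp$lagrangian
  blk <- sp$lagrangian_outer
  scale <- max(abs(lag))
  for (b in unique(blk)) {
    v <- lag[blk == b]
    if (length(v) > 1) expect_true(all(diff(v) <= 1e-9 * scale))
  }
})

test_that("the estimated rank is invariant to positive rescaling", {
  sim <- simulate_lowrank_sparse(lowrank_sim_config(50, 60, 4, 0.05,
                                                    seed = 5))
  expect_equal(ealm_decompose(sim$X)$s, ealm_decompose(1e3 * sim$X)$s)
})

test_that("noiseless sinusoid trajectories estimate two components per tone", {
  t <- (0:899) / 30
  one <- build_trajectory(sin(2 * pi * 1.2 * t), 90)
  expect_equal(ealm_decompose(one)$s, 2)
  two <- build_trajectory(sin(2 * pi * 1.2 * t) + 0.8 * sin(2 * pi * 0.8 * t),
                          90)
  expect_equal(ealm_decompose(two)$s, 4)
})

test_that("the printed dimension-reciprocal sparsity weight degenerates", {
  # with eta = 1/max(m,n) the l1 penalty is so weak that the sparse part
  # absorbs the matrix; kept as an option, not the default
  sim <- simulate_lowrank_sparse(lowrank_sim_config(100, 120, 5, 0.05,
                                                    seed = 1))
  sp <- ealm_decompose(sim$X, ealm_config(eta_mode = "dims"))
  expect_lt(sp$s, 5)
  expect_gt(norm(sp$A - sim$A_true, "F") / norm(sim$A_true, "F"), 0.5)
})

test_that("config validation enforces the documented ranges", {
  expect_error(ealm_config(rho_growth = 1.05), "rho_growth")
  expect_error(ealm_config(rho_growth = 2.5), "rho_growth")
  expect_error(ealm_config(tol = -1), "tol")
  expect_error(ealm_decompose(matrix(0, 3, 3)), "nonzero")
})
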