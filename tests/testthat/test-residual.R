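test_that("analytic-derivative residual matches a pure finite-difference evaluation", {
  fpe1 <- fpe_model(continuous_model(toy_network("single_gene")), omega = 50)
  mix1 <- gamma_mixture(1, 48, 50)
  set.seed(13)
  for (p in runif(6, 0.3, 3)) {
    a <- stationary_residual(fpe1, mix1, p)
    b <- fd_residual(fpe1, mix1, p)
    expect_lt(abs(a - b) / max(abs(b), 1e-10), 1e-4)
  }
  # 2-D, two components, including a Gaussian proxy
  fpe2 <- fpe_model(bistable_toggle_model(), omega = 50)
  mix2 <- gamma_mixture(c(0.5, 0.5), rbind(c(60, 8), c(8, 60)),
                        rbind(c(30, 16), c(16, 30)))
  gm2 <- gaussian_mixture(c(0.5, 0.5), rbind(c(1.9, 0.45), c(0.45, 1.9)),
                          rbind(c(0.05, 0.03), c(0.03, 0.05)))
  for (rep in 1:6) {
    p <- runif(2, 0.2, 2.5)
    for (m in list(mix2, gm2)) {
      a <- stationary_residual(fpe2, m, p)
      b <- fd_residual(fpe2, m, p)
      expect_lt(abs(a - b) / max(abs(b), 1e-10), 1e-4)
    }
  }
})

test_that("the residual operator is linear in the density", {
  fpe <- fpe_model(continuous_model(toy_network("single_gene")), omega = 50)
  m1 <- gamma_mixture(1, 40, 45)
  m2 <- gamma_mixture(1, 60, 55)
  pts <- matrix(seq(0.3, 3, length.out = 9), ncol = 1)
  R1 <- stationary_residual(fpe, m1, pts)
  R2 <- stationary_residual(fpe, m2, pts)
  mixed <- gamma_mixture(c(0.3, 0.7), rbind(40, 60), rbind(45, 55))
  expect_equal(stationary_residual(fpe, mixed, pts), 0.3 * R1 + 0.7 * R2,
               tolerance = 1e-10)
})

test_that("the grid-oracle density nearly annihilates the residual; misplaced densities do not", {
  fpe <- fpe_model(continuous_model(toy_network("single_gene")), omega = 50)
  gs <- grid_stationary(fpe, box = rbind(0, 4), n_grid = 801)
  oracle <- interpolated_density(gs)
  pts <- matrix(seq(0.4, 2, by = 0.1), ncol = 1)
  r_oracle <- mean(abs(stationary_residual(fpe, oracle, pts)))
  wrong <- gamma_mixture(1, 1, 1)  # unit exponential, far from the attractor
  r_wrong <- mean(abs(stationary_residual(fpe, wrong, pts)))
  expect_lt(r_oracle, 1e-2)
  expect_gt(r_wrong, 10 * r_oracle)
})

test_that("boundary points are rejected for gamma trial densities", {
  fpe <- fpe_model(continuous_model(toy_network("single_gene")), omega = 50)
  expect_error(stationary_residual(fpe, gamma_mixture(1, 0.5, 1), 0),
               "strictly inside")
})

test_that("the collocation norm is a seeded nonnegative Monte Carlo estimate", {
  fpe <- fpe_model(continuous_model(toy_network("single_gene")), omega = 50)
  mix <- gamma_mixture(1, 48, 50)
  cc <- collocation_config(n_points = 2000, p_max = 10, seed = 31)
  v1 <- collocation_residual_norm(fpe, mix, cc)
  v2 <- collocation_residual_norm(fpe, mix, cc)
  expect_identical(as.numeric(v1), as.numeric(v2))
  expect_gte(as.numeric(v1), 0)
  expect_identical(attr(v1, "n_points"), 2000L)
  # mean_abs * volume = norm under uniform sampling
  expect_equal(as.numeric(v1), attr(v1, "mean_abs") * 10)
  # oracle-shaped density scores below a misplaced one
  v_wrong <- collocation_residual_norm(fpe, gamma_mixture(1, 1, 1), cc)
  expect_lt(as.numeric(v1), as.numeric(v_wrong))
})

test_that("the Monte Carlo error of the norm shrinks like 1/sqrt(n)", {
  fpe <- fpe_model(continuous_model(toy_network("single_gene")), omega = 50)
  mix <- gamma_mixture(1, 30, 35)
  est <- function(n, s) as.numeric(collocation_residual_norm(
    fpe, mix, collocation_config(n, 10, seed = s)))
  small <- vapply(1:24, est, numeric(1), n = 500)
  large <- vapply(1:24, est, numeric(1), n = 8000)
  ratio <- sd(small) / sd(large)  # expected sqrt(16) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("proxy importance sampling agrees with uniform sampling in expectation", {
  fpe <- fpe_model(continuous_model(toy_network("single_gene")), omega = 50)
  mix <- gamma_mixture(1, 48, 50)
  proxy <- gaussian_mixture(1, 1, 0.2)
  u <- as.numeric(collocation_residual_norm(
    fpe, mix, collocation_config(2e4, 10, seed = 1)))
  ip <- as.numeric(collocation_residual_norm(
    fpe, mix, collocation_config(2e4, 10, "proxy", seed = 2), proxy = proxy))
  expect_equal(ip, u, tolerance = 0.15)
})
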