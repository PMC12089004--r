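test_that("construction validates parameters; evaluation does not", {
  expect_error(gamma_mixture(1, -1, 1), "strictly positive")
  expect_error(gamma_mixture(1, 1, 0), "strictly positive")
  expect_error(gamma_mixture(c(-0.1, 1.1), rbind(1, 1), rbind(1, 1)),
               "nonnegative")
  expect_error(gaussian_mixture(1, 0, 0), "variances")
  # weights are renormalized onto the simplex
  m <- gamma_mixture(c(2, 6), rbind(c(1, 2), c(3, 4)), rbind(c(1, 1), c(1, 1)))
  expect_equal(m$weights, c(0.25, 0.75))
})

test_that("density values match closed forms", {
  m <- gamma_mixture(1, 1, 1)
  expect_equal(mixture_pdf(m, 0.5), exp(-0.5))
  expect_equal(mixture_pdf(m, 2, log = TRUE), -2)
  expect_error(mixture_pdf(m, -1), "nonnegative")
  # mass split of two well-separated components follows the weights
  m2 <- gamma_mixture(c(0.3, 0.7), rbind(50, 400), rbind(50, 100))
  mid <- 2.5
  set.seed(2)
  x <- mixture_sample(m2, 2e4, seed = 2)
  expect_equal(mean(x < mid), 0.3, tolerance = 0.02)
  # same split via the closed-form gamma CDF
  expect_equal(0.3 * pgamma(mid, 50, 50) + 0.7 * pgamma(mid, 400, 100),
               0.3, tolerance = 1e-6)
})

test_that("the density integrates to 1 (2-D Monte Carlo)", {
  m <- gamma_mixture(c(0.4, 0.6), rbind(c(2, 5), c(8, 3)),
                     rbind(c(1, 2), c(3, 1)))
  set.seed(7)
  n <- 1e5
  box <- 25
  P <- matrix(runif(2 * n, 0, box), n, 2)
  v <- mixture_pdf(m, P) * box^2
  expect_lt(abs(mean(v) - 1), 3 * sd(v) / sqrt(n))
})

test_that("sampling is seeded and consistent with the density", {
  m <- gamma_mixture(1, c(4, 9), c(2, 3))
  x <- mixture_sample(m, 4e4, seed = 5)
  expect_identical(x, mixture_sample(m, 4e4, seed = 5))
  # per-coordinate means hit alpha/beta within 3 standard errors
  for (j in 1:2) {
    mu <- m$shapes[1, j] / m$rates[1, j]
    se <- sqrt(m$shapes[1, j] / m$rates[1, j]^2 / nrow(x))
    expect_lt(abs(mean(x[, j]) - mu), 3 * se)
  }
  # coordinates are independent within a component
  expect_lt(abs(cor(x[, 1], x[, 2])), 3 / sqrt(nrow(x)))
  # histogram matches the marginal density (chi-square)
  br <- qgamma(seq(0, 1, length.out = 21), 4, 2)
  obs <- table(cut(x[, 1], br))
  expect_gt(chisq.test(obs, p = rep(1 / 20, 20))$p.value, 1e-3)
})

test_that("opposite on/off expression patterns induce positive co-activation correlations", {
  # two attractors: genes (1,2) on together in one, off together in the other
  m <- gamma_mixture(c(0.5, 0.5), rbind(c(50, 50), c(1, 1)),
                     rbind(c(25, 25), c(10, 10)))
  x <- mixture_sample(m, 2e4, seed = 9)
  expect_gt(cor(x[, 1], x[, 2]), 0.5)
})

test_that("modes and active-gene summaries follow the gamma mode formula", {
  expect_equal(unname(mixture_modes(gamma_mixture(1, 5.83, 1.88))[1, 1]),
               2.569149, tolerance = 1e-6)
  expect_equal(unname(mixture_modes(gamma_mixture(1, 1, 2))[1, 1]), 0)
  expect_equal(unname(mixture_modes(gamma_mixture(1, 3, 1))[1, 1]), 2)
  # all-exponential component: no active genes
  expect_equal(active_gene_summary(gamma_mixture(1, c(1, 1), c(1, 2))), 0)
  # fixture mixture reproduces the published per-attractor summaries
  tm <- at_table2_mixture()
  expect_equal(active_gene_summary(tm), c(1.9, 2.5, 1.8, 1.9),
               tolerance = 0.031)
})

test_that("landscape is the negative log density", {
  m <- gamma_mixture(1, 1, 1)
  x <- c(0.3, 1, 4)
  expect_equal(landscape(m, matrix(x, ncol = 1)), x)  # U(p) = p
  # the global mode has the lowest landscape value among samples
  m2 <- gamma_mixture(c(0.6, 0.4), rbind(c(40, 2), c(3, 60)),
                      rbind(c(20, 2), c(2, 30)))
  smp <- mixture_sample(m2, 1e4, seed = 4)
  U_mode <- min(landscape(m2, mixture_modes(m2)))
  expect_lte(U_mode, min(landscape(m2, smp)) + 1e-9)
  # well-depth difference of identically shaped far-apart wells is
  # log(w1/w2) (Gaussian components translate without changing shape)
  m3 <- gaussian_mixture(c(0.9, 0.1), rbind(1, 10), rbind(0.04, 0.04))
  U <- landscape(m3, mixture_modes(m3))
  expect_equal(U[2] - U[1], log(9), tolerance = 1e-6)
})

test_that("landscape summary yields Manhattan distances and finite depths", {
  m <- gamma_mixture(c(0.5, 0.5), rbind(c(2, 2), c(2, 2)),
                     rbind(c(1, 1), c(1, 1)))
  ls <- landscape_summary(m)
  expect_equal(ls$distances, matrix(0, 2, 2))  # identical components
  m2 <- gamma_mixture(c(0.5, 0.5), rbind(2, 9), rbind(1, 2))  # modes 1 and 4
  expect_equal(landscape_summary(m2)$distances[1, 2], 3)
  ls_at <- landscape_summary(at_table2_mixture())
  off <- ls_at$distances[upper.tri(ls_at$distances)]
  expect_true(all(off > 0))
  expect_true(all(is.finite(ls_at$depths)))
})

test_that("the Gaussian proxy supports the same interface", {
  g <- gaussian_mixture(c(0.5, 0.5), rbind(c(1, 2), c(3, 4)),
                        rbind(c(0.1, 0.1), c(0.2, 0.2)))
  expect_equal(mixture_modes(g), g$means, ignore_attr = TRUE)
  x <- mixture_sample(g, 1e4, seed = 1)
  expect_equal(colMeans(x), c(2, 3), tolerance = 0.15, ignore_attr = TRUE)
  # density integrates to 1 on a generous box
  set.seed(3)
  P <- cbind(runif(2e4, -3, 7), runif(2e4, -2, 8))
  v <- mixture_pdf(g, P) * 100
  expect_lt(abs(mean(v) - 1), 3 * sd(v) / sqrt(2e4))
})

test_that("mixture JSON round trip is exact", {
  tm <- at_table2_mixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_mixture_json(tm, path)
  back <- read_mixture_json(path)
  expect_equal(back$shapes, tm$shapes)
  expect_equal(back$rates, tm$rates)
  expect_identical(back$genes, tm$genes)
  g <- gaussian_mixture(1, c(1, 2), c(3, 4))
  write_mixture_json(g, path)
  expect_equal(read_mixture_json(path)$variances, g$variances)
})
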