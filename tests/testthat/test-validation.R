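test_that("Pearson matrices are symmetric, unit-diagonal, and exact on linear data", {
  M <- pearson_matrix(cbind(a = c(0, 1, 2), b = c(0, 2, 4)))
  expect_equal(M$values[1, 2], 1)
  expect_equal(diag(M$values), c(a = 1, b = 1))
  # independent columns decorrelate at the 3/sqrt(m) scale
  set.seed(4)
  X <- matrix(rexp(3 * 1e5), ncol = 3)
  Mi <- pearson_matrix(X)
  expect_lt(max(abs(Mi$values[upper.tri(Mi$values)])), 3 / sqrt(1e5))
  # constant column yields 0 with a warning
  expect_warning(Mc <- pearson_matrix(cbind(x = c(1, 1, 1), y = c(1, 2, 3))),
                 "constant")
  expect_equal(Mc$values[1, 2], 0)
  expect_error(pearson_matrix(matrix(1:4, 2, 2)), "at least 3")
  # scale/shift invariance
  set.seed(5)
  Y <- matrix(rnorm(300), ncol = 3)
  M1 <- pearson_matrix(Y)
  M2 <- pearson_matrix(sweep(sweep(Y, 2, c(2, 0.5, 10), `*`), 2,
                             c(-1, 3, 0), `+`))
  expect_equal(M1$values, M2$values, tolerance = 1e-12)
})

test_that("coexpression sampled from a mixture reflects its co-activation structure", {
  m <- gamma_mixture(c(0.5, 0.5),
                     rbind(c(50, 50, 1), c(1, 1, 50)),
                     rbind(c(25, 25, 10), c(10, 10, 25)),
                     genes = c("a", "b", "c"))
  M <- pearson_matrix(mixture_sample(m, 2e4, seed = 8))
  expect_gt(M$values["a", "b"], 0.5)   # co-activated pair
  expect_lt(M$values["a", "c"], -0.5)  # anti-activated pair
})

test_that("the matrix distance is a metric computed over all entries", {
  M <- correlation_matrix(matrix(c(1, 0.6, 0.6, 1), 2), c("a", "b"))
  I2 <- correlation_matrix(diag(2), c("a", "b"))
  expect_equal(matrix_distance(M, M), 0)
  expect_equal(matrix_distance(I2, M), sqrt(2 * 0.36))
  # metric axioms on random triples
  set.seed(6)
  for (rep in 1:10) {
    tri <- lapply(1:3, function(k) random_correlation_matrix(5, 40))
    d12 <- matrix_distance(tri[[1]], tri[[2]])
    d13 <- matrix_distance(tri[[1]], tri[[3]])
    d23 <- matrix_distance(tri[[2]], tri[[3]])
    expect_equal(d12, matrix_distance(tri[[2]], tri[[1]]))
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_gt(d12, 0)
  }
  # label alignment: reordering is tolerated, disjoint labels are not
  M2 <- correlation_matrix(matrix(c(1, 0.6, 0.6, 1), 2), c("b", "a"))
  expect_equal(matrix_distance(M, M2),
               matrix_distance(M$values, M$values[2:1, 2:1]))
  M3 <- correlation_matrix(diag(2), c("x", "y"))
  expect_error(matrix_distance(M, M3), "unmatched")
})

test_that("random correlation matrices satisfy the invariants and concentrate with m_eff", {
  R <- random_correlation_matrix(6, 50, seed = 9)
  v <- R$values
  expect_equal(v, t(v))
  expect_equal(diag(v), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(abs(v) <= 1))
  expect_true(all(eigen(v, only.values = TRUE)$values > -1e-10))  # PSD
  expect_identical(v, random_correlation_matrix(6, 50, seed = 9)$values)
  big <- random_correlation_matrix(6, 1e5, seed = 10)$values
  expect_lt(max(abs(big[upper.tri(big)])), 3 / sqrt(1e5))
})

test_that("null distance distributions behave as advertised", {
  M_e <- random_correlation_matrix(6, 30, seed = 1)
  expect_error(null_distance_distributions(M_e, n_draws = 10), "100")
  nd <- null_distance_distributions(M_e, n_draws = 200, m_eff = 50, seed = 2)
  bound <- sqrt(2 * choose(6, 2) * 4)
  for (x in nd) {
    expect_true(all(x$samples >= 0))
    expect_true(all(x$samples <= bound))
  }
  nd2 <- null_distance_distributions(M_e, n_draws = 200, m_eff = 50, seed = 2)
  expect_identical(nd$random_vs_random$samples,
                   nd2$random_vs_random$samples)
  # with M_e = identity, random-vs-random distances are sqrt(2) larger in
  # mean than identity-vs-random (entrywise differences of two independent
  # fluctuating matrices have twice the variance of one)
  I6 <- correlation_matrix(diag(6))
  ndI <- null_distance_distributions(I6, n_draws = 400, m_eff = 2000,
                                     seed = 3)
  expect_equal(mean(ndI$random_vs_random$samples) /
                 mean(ndI$experimental_vs_random$samples),
               sqrt(2), tolerance = 0.05)
})

test_that("validation verdicts follow the percentile policy", {
  M_e <- random_correlation_matrix(8, 40, seed = 11)
  # identical model matrix: distance 0, bottom percentile, clearly non-random
  rep0 <- validate_model(M_e, M_e, n_draws = 300, m_eff = 40, seed = 12)
  expect_equal(rep0$D, 0)
  expect_lt(rep0$percentile[["experimental_vs_random"]], 0.01)
  expect_identical(rep0$verdict, "discriminated from random")
  # an unrelated random matrix lands inside its own null
  M_m <- random_correlation_matrix(8, 40, seed = 13)
  rep1 <- validate_model(M_m, M_e, n_draws = 300, m_eff = 40, seed = 12)
  expect_gt(rep1$percentile[["experimental_vs_random"]], 0.001)
  expect_identical(rep1$verdict, "cannot be discarded")
  # a matrix far beyond the null is discarded: flip the sign pattern hard
  v <- M_e$values
  far <- correlation_matrix(0.98 * (2 * diag(8) - 1) + 0.02 * v, M_e$labels,
                            tol = 1)
  rep2 <- validate_model(far, M_e, n_draws = 300, m_eff = 4000, seed = 12)
  expect_identical(rep2$verdict, "discard")
})

test_that("coexpression CSV round trip, missing data, and reordering", {
  M <- random_correlation_matrix(5, 60, seed = 14,
                                 labels = c("d", "b", "a", "c", "e"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_coexpression_csv(M, path)
  back <- read_coexpression_csv(path)
  expect_equal(back$values, M$values, tolerance = 1e-12)
  # caller-specified gene order
  ord <- c("a", "b", "c", "d", "e")
  reord <- read_coexpression_csv(path, gene_order = ord)
  expect_identical(reord$labels, ord)
  expect_equal(reord$values, M$values[ord, ord], tolerance = 1e-12)
  expect_error(read_coexpression_csv(path,
                                     gene_order = c("a", "b", "c", "d", "f")),
               "unmatched")
  # an empty cell reads as 0 (missing coexpression data)
  txt <- "gene,a,b\na,1,\nb,,1\n"
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, p2)
  M2 <- read_coexpression_csv(p2)
  expect_equal(M2$values["a", "b"], 0)
  # asymmetry is averaged with a warning
  txt3 <- "gene,a,b\na,1,0.5\nb,0.3,1\n"
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt3, p3)
  expect_warning(M3 <- read_coexpression_csv(p3), "asymmetry")
  expect_equal(M3$values["a", "b"], 0.4)
})
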