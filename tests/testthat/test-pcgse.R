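test_that("gene-level statistics are scaled Fisher transforms", {
  # a column exactly proportional to the PC scores has r = 1 (clipped)
  n <- 50
  set.seed(4)
  s <- rnorm(n)
  x <- cbind(a = s * 2, b = rnorm(n), c = -s)
  z <- gene_level_statistics(scale(x), s)
  expect_true(is.finite(z[1L]) && z[1L] > 0)
  expect_true(is.finite(z[3L]) && z[3L] < 0)
  # r = 0.5 at n = 50 gives sqrt(47) * atanh(0.5)
  r <- cor(x[, 2L], s)
  expect_equal(z[2L], sqrt(47) * atanh(r))
  expect_equal(sqrt(47) * atanh(0.5), 3.76589, tolerance = 1e-5)
  # antisymmetry under PC sign flip
  expect_equal(gene_level_statistics(scale(x), -s), -z)
  expect_error(gene_level_statistics(scale(x)[1:3, ], s[1:3]), "n >= 4")
  expect_error(gene_level_statistics(scale(x), rep(1, n)), "constant")
})

test_that("mean pairwise correlation behaves at its extremes", {
  set.seed(6)
  base <- rnorm(30)
  x <- cbind(base, base, base, rnorm(30))
  expect_equal(mean_pairwise_correlation(x, 1:3), 1)
  expect_error(mean_pairwise_correlation(x, 1L), "at least 2")
  # independent population: the average estimate is near zero
  rhos <- vapply(1:50, function(i) {
    set.seed(100 + i)
    mean_pairwise_correlation(matrix(rnorm(50 * 20), 50, 20), 1:20)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 3 / sqrt(50))
  # single-factor design: population pairwise member correlation is
  # (4 * 0.05) / (4 * 0.05 + 1) = 1/6
  rhos_f <- vapply(1:50, function(i) {
    x <- simulate_dataset(covariance_model("single_factor"), 50,
                          seed = 500 + i)
    mean_pairwise_correlation(standardize(x), 1:20)
  }, numeric(1))
  expect_lt(abs(mean(rhos_f) - 1 / 6), 0.06)
})

test_that("the correlation-adjusted set test reduces to the pooled t-test", {
  set.seed(7)
  z <- rnorm(100)
  mem <- rep(c(TRUE, FALSE), c(20, 80))
  res <- set_test(z, mem, rho_bar = 0)
  oracle <- pooled_t_oracle(z, mem)
  expect_equal(res$t_stat, oracle$t, tolerance = 1e-12)
  expect_equal(res$pvalue, oracle$p, tolerance = 1e-12)
  expect_identical(res$df, 98L)
  expect_equal(res$vif, 1)
  # VIF arithmetic: m = 20, rho = 1/6
  res2 <- set_test(z, mem, rho_bar = 1 / 6)
  expect_equal(res2$vif, 1 + 19 / 6)
  expect_lt(abs(res2$t_stat), abs(res$t_stat))
  # negative rho is floored, not allowed to deflate the variance
  expect_equal(set_test(z, mem, rho_bar = -0.3)$vif, 1)
  # identical group means give t = 0, p = 1
  z0 <- rep(c(1, -1), 50)
  expect_equal(set_test(z0, mem, 0)$t_stat, 0)
  expect_equal(set_test(z0, mem, 0)$pvalue, 1)
  expect_error(set_test(z, rep(1, 100), 0), "1 <= m < p")
  expect_error(set_test(z, rep(0, 100), 0), "1 <= m < p")
})

test_that("the per-PC p-value matrix is well-formed and sign-invariant", {
  x <- simulate_dataset(covariance_model("single_factor"), n = 50, seed = 8)
  xs <- standardize(x)
  sp <- compute_spectra(xs)
  sets <- make_gene_sets(200, 10, 20)
  P <- pcgse_matrix(xs, sp, sets, sp$rank)
  expect_identical(dim(P), c(10L, 49L))
  expect_true(all(P >= 0 & P <= 1))
  # flipping the sign of a PC leaves every set p-value unchanged
  sp_flip <- sp
  sp_flip$scores[, 3L] <- -sp_flip$scores[, 3L]
  sp_flip$loadings[, 3L] <- -sp_flip$loadings[, 3L]
  expect_equal(pcgse_matrix(xs, sp_flip, sets, sp$rank), P)
  # the factor gene set is strongly associated with PC 1, the others not
  expect_lt(P[1L, 1L], 1e-3)
  expect_gt(min(P[2:10, 1L]), 1e-3)
  expect_error(pcgse_matrix(xs, sp, sets, 60), "exceeds rank")
})

test_that("per-PC p-values are calibrated under the identity null", {
  # competitive test of one fixed (set, PC) cell over replicated null
  # datasets: approximately uniform, slightly conservative at the tail
  model <- covariance_model("identity")
  sets <- make_gene_sets(200, 10, 20)
  set.seed(15)
  seeds <- sample.int(2^31 - 2, 400)
  cell <- vapply(seeds, function(s) {
    xs <- standardize(simulate_dataset(model, 50, seed = s))
    pcgse_matrix(xs, compute_spectra(xs), sets, 1L)[1L, 1L]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(cell, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
  rate <- mean(cell < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)
})
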