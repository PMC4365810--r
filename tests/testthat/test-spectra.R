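test_that("standardization centers and scales columns", {
  expect_equal(standardize(matrix(c(1, 2, 3, 5, 5, 8), 3, 2))[, 1L],
               c(-1, 0, 1))
  set.seed(1)
  s <- standardize(matrix(rnorm(60, mean = 5, sd = 3), 10, 6))
  expect_true(all(abs(colMeans(s)) < 1e-12))
  expect_equal(apply(s, 2L, sd), rep(1, 6), ignore_attr = TRUE)
  m <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
              dimnames = list(NULL, c("ok", "flat")))
  expect_error(standardize(m), "flat")
})

test_that("spectral decomposition matches correlation-matrix eigenstructure", {
  # closed form for two variables: eigenvalues are 1 +/- rho
  set.seed(3)
  m <- matrix(rnorm(40), 20, 2)
  rho <- cor(m)[1L, 2L]
  sp <- compute_spectra(standardize(m))
  expect_equal(sp$eigenvalues, c(1 + abs(rho), 1 - abs(rho)))

  x <- standardize(toy_expression(n = 15, p = 8)$values)
  sp <- compute_spectra(x)
  expect_equal(sum(sp$eigenvalues), 8, tolerance = 1e-8)  # trace of cor
  expect_equal(crossprod(sp$loadings), diag(sp$rank), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(apply(sp$scores, 2L, var), sp$eigenvalues,
               ignore_attr = TRUE, tolerance = 1e-8)
  # rank-restricted reconstruction of the correlation matrix
  recon <- sp$loadings %*% (sp$eigenvalues * t(sp$loadings))
  expect_lt(norm(recon - cor(x), "F"), 1e-8 * ncol(x))
})

test_that("a generic centered 50 x 200 matrix has rank 49", {
  set.seed(11)
  sp <- compute_spectra(standardize(matrix(rnorm(50 * 200), 50, 200)))
  expect_identical(sp$rank, 49L)
})

test_that("the decomposition is invariant to column scale and row order", {
  x <- toy_expression(n = 12, p = 7)$values
  sp <- compute_spectra(standardize(x))
  x_scaled <- sweep(x, 2L, c(2, 0.1, 7, 1, 3, 0.5, 10), "*")
  sp2 <- compute_spectra(standardize(x_scaled))
  expect_equal(sp2$eigenvalues, sp$eigenvalues)
  expect_equal(sp2$loadings, sp$loadings)
  perm <- c(5, 1, 12, 3, 2, 11, 8, 6, 4, 10, 9, 7)
  sp3 <- compute_spectra(standardize(x[perm, ]))
  expect_equal(sp3$eigenvalues, sp$eigenvalues)
  expect_equal(sp3$loadings, sp$loadings)
  expect_equal(sp3$scores, sp$scores[perm, ], ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading entry is positive
  expect_true(all(apply(sp$loadings, 2L, function(v)
    v[which.max(abs(v))] > 0)))
})

test_that("Tracy-Widom rescaling follows the eigenvalue index", {
  # mu(20, 50) = (sqrt(49) + sqrt(20))^2 / 50 and the matching sigma
  mu <- (sqrt(49) + sqrt(20))^2 / 50
  sigma <- ((sqrt(49) + sqrt(20)) / 50) * (1 / sqrt(49) + 1 / sqrt(20))^(1 / 3)
  expect_equal(mu, 2.6321981, tolerance = 1e-6)
  expect_equal(sigma, 0.1641918, tolerance = 1e-6)
  expect_equal(tw_rescale(mu, 1, n = 50, p = 20), 0)
  expect_equal(tw_rescale(3, 1, n = 50, p = 20), (3 - mu) / sigma)
  # index shifts the effective dimension: i = 3 with p = 20 uses p_eff = 18
  mu18 <- (sqrt(49) + sqrt(18))^2 / 50
  expect_equal(tw_rescale(mu18, 3, n = 50, p = 20), 0)
  # continuity across the p_eff = n boundary (dimensions swap smoothly)
  tws <- sapply(10:12, function(i) tw_rescale(2, i, n = 50, p = 61))
  expect_lt(max(abs(diff(tws))), 0.5)
  expect_error(tw_rescale(2, 0, 50, 20), "index_i")
  expect_error(tw_rescale(2, 55, 50, 200), "index_i")
})

test_that("the TW1 CDF approximation matches the Painleve II oracle", {
  expect_equal(ptw1(-40), 0)
  expect_equal(ptw1(40), 1)
  grid <- seq(-6, 6, length.out = 1000)
  expect_true(all(diff(ptw1(grid)) > 0))
  # shifted-Gamma moment matching is accurate to ~1e-3 over the support
  expect_lt(max(abs(ptw1(tw1_oracle$t) - tw1_oracle$F)), 1.2e-3)
  expect_equal(ptw1(2, lower.tail = FALSE), 1 - ptw1(2))
})

test_that("PC significance returns complementary tails and detects spikes", {
  x <- simulate_dataset(covariance_model("single_factor"), n = 50, seed = 2)
  sig <- pc_significance(compute_spectra(standardize(x)))
  expect_equal(sig$upper_pvalues + sig$lower_cdf,
               rep(1, length(sig$tw_stats)))
  expect_true(all(sig$upper_pvalues >= 0 & sig$upper_pvalues <= 1))

  # under the null the leading-eigenvalue test is conservative; under the
  # single-factor spike it rejects far more often (the spike is only
  # slightly above the detectability edge, so the rate is well below 1)
  set.seed(14)
  seeds <- sample.int(2^31 - 2, 120)
  rej <- function(model) mean(vapply(seeds, function(s) {
    x <- simulate_dataset(model, n = 50, seed = s)
    pc_significance(compute_spectra(standardize(x)))$upper_pvalues[1L] < 0.05
  }, logical(1)))
  null_rate <- rej(covariance_model("identity"))
  spike_rate <- rej(covariance_model("single_factor"))
  expect_lte(null_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
  expect_gt(spike_rate, 0.3)
  expect_gt(spike_rate, null_rate + 0.2)
})

test_that("PC selection honors the three modes and their constraints", {
  x <- standardize(simulate_dataset(covariance_model("identity"),
                                    n = 50, seed = 9))
  sp <- compute_spectra(x)
  sig <- pc_significance(sp)
  expect_identical(select_pcs(sp, sig, pc_selection("all_nonzero")), 49L)
  expect_identical(select_pcs(sp, sig, pc_selection("fixed", q_star = 2)), 2L)
  expect_error(select_pcs(sp, sig, pc_selection("fixed", q_star = 100)),
               "exceeds the number of PCs")
  expect_error(select_pcs(sp, sig, pc_selection("significant", alpha = 1e-12)),
               "no PC is significant")
  xf <- standardize(simulate_dataset(covariance_model("single_factor"),
                                     n = 50, seed = 21))
  spf <- compute_spectra(xf)
  sigf <- pc_significance(spf)
  q <- select_pcs(spf, sigf, pc_selection("significant", alpha = 0.5))
  expect_true(q >= 1L && q <= spf$rank)
})
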