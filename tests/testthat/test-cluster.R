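test_that("chi-squared enrichment matches the textbook statistic", {
  set.seed(17)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    sizes <- sample(5:40, k, replace = TRUE)
    labels <- rep(seq_len(k), sizes)
    mem <- as.integer(seq_along(labels) %in%
                        sample(length(labels), sample(3:15, 1)))
    tab <- rbind(tabulate(labels[mem == 1L], k), tabulate(labels, k))
    oracle <- chisq_oracle(tab)
    expect_equal(chisq_enrichment(labels, mem, k = k), oracle$p,
                 tolerance = 1e-10)
  }
  # hand-checked 2x2 'paper' table: rows (10, 0) and (20, 20)
  labels <- rep(1:2, each = 20)
  mem <- c(rep(1, 10), rep(0, 30))
  tab <- rbind(c(10, 0), c(20, 20))
  expect_equal(chisq_enrichment(labels, mem, k = 2),
               chisq_oracle(tab)$p, tolerance = 1e-10)
  # complement style uses the disjoint table
  tabc <- rbind(c(10, 0), c(10, 20))
  expect_equal(chisq_enrichment(labels, mem, k = 2,
                                table_style = "complement"),
               chisq_oracle(tabc)$p, tolerance = 1e-10)
})

test_that("chi-squared enrichment is invariant and degenerate-safe", {
  # member counts proportional to cluster sizes: independence exactly
  labels <- rep(1:2, c(30, 60))
  mem <- c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 40))
  expect_equal(chisq_enrichment(labels, mem, k = 2), 1)
  # permuting cluster labels permutes table columns only
  set.seed(19)
  labels2 <- sample(1:3, 80, replace = TRUE)
  mem2 <- as.integer(seq_len(80) %in% sample(80, 12))
  relab <- c(3L, 1L, 2L)[labels2]
  expect_equal(chisq_enrichment(relab, mem2, k = 3),
               chisq_enrichment(labels2, mem2, k = 3))
  expect_error(chisq_enrichment(rep(1L, 50), mem2[1:50], k = 1),
               "single cluster")
})

test_that("k-means clustering is reproducible and improves with restarts", {
  x <- simulate_dataset(covariance_model("single_factor"), n = 50, seed = 3)
  c1 <- cluster_variables(x$values, k_mode = "fixed", k_fixed = 2, seed = 7)
  c2 <- cluster_variables(x$values, k_mode = "fixed", k_fixed = 2, seed = 7)
  expect_identical(c1$labels, c2$labels)
  expect_identical(sort(unique(c1$labels)), 1:2)
  # with the same seed the first start is shared, so best-of-10 can never
  # be worse than the single-start solution
  w1 <- cluster_variables(x$values, k_mode = "fixed", k_fixed = 3,
                          restarts = 1, seed = 5)$tot_withinss
  w10 <- cluster_variables(x$values, k_mode = "fixed", k_fixed = 3,
                           restarts = 10, seed = 5)$tot_withinss
  expect_lte(w10, w1 + 1e-8)
})

test_that("the gap statistic finds the obvious and refuses the absent", {
  # two tight, well-separated blobs of variables
  set.seed(8)
  blob <- cbind(matrix(rnorm(8 * 15), 8, 15),
                matrix(rnorm(8 * 15, mean = 6), 8, 15))
  cl <- cluster_variables(blob, k_mode = "gap", k_max = 5, n_boot = 50,
                          seed = 4)
  expect_identical(cl$k, 2L)
  expect_identical(nrow(cl$gap_curve), 5L)
  # two-factor simulated data carry no k-means-visible cluster structure
  x2 <- simulate_dataset(covariance_model("two_factor"), n = 50, seed = 99)
  cl2 <- cluster_variables(x2$values, k_mode = "gap", k_max = 5,
                           n_boot = 50, seed = 3)
  expect_identical(cl2$k, 1L)
  # enrichment against that clustering is refused
  sets <- make_gene_sets(200, 10, 20)
  expect_error(cluster_enrich(x2, sets, k = "gap", k_max = 5, n_boot = 50,
                              seed = 3),
               "undefined for k = 1")
})

test_that("cluster enrichment is deterministic and detects the factor set", {
  x <- simulate_dataset(covariance_model("single_factor"), n = 50, seed = 3)
  sets <- make_gene_sets(200, 10, 20)
  ce1 <- cluster_enrich(x, sets, k = 2, seed = 42)
  ce2 <- cluster_enrich(x, sets, k = 2, seed = 42)
  expect_identical(ce1$pvalues, ce2$pvalues)
  expect_length(ce1$pvalues, 10L)
  expect_true(all(ce1$pvalues >= 0 & ce1$pvalues <= 1))
  expect_lt(ce1$pvalues[["set1"]], 0.05)
})
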