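# Independent oracles and shared fixtures for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tracy-Widom order-1 CDF values computed by numerical integration of the
# Painleve II representation (Hastings-McLeod solution; F1(s)^2 =
# F2(s) * exp(-int_s^Inf q dt)), frozen here. The integration reproduces
# the published TW1 percentiles 0.4501 -> 0.90, 0.9793 -> 0.95,
# 2.0234 -> 0.99 and the median -1.2686 -> 0.50.
tw1_oracle <- data.frame(
  t = c(-3.5, -3.0, -2.5, -2.0, -1.5, -1.0, -0.5, 0.0, 0.5, 1.0, 1.5,
        2.0, 3.0),
  F = c(0.02589417, 0.06960014, 0.15137775, 0.27432021, 0.42622582,
        0.58378991, 0.72369106, 0.83190807, 0.90597119, 0.95142124,
        0.97671366, 0.98959758, 0.99829349)
)

# textbook pooled two-sample t-test on gene-level statistics (no
# correlation adjustment); oracle for the rho_bar = 0 limit of set_test()
pooled_t_oracle <- function(stats_values, mem) {
  z1 <- stats_values[mem]
  z2 <- stats_values[!mem]
  m <- length(z1)
  k <- length(z2)
  sp <- sqrt(((m - 1) * var(z1) + (k - 1) * var(z2)) / (m + k - 2))
  t <- (mean(z1) - mean(z2)) / (sp * sqrt(1 / m + 1 / k))
  list(t = t, p = 2 * pt(-abs(t), df = m + k - 2))
}

# textbook Pearson chi-squared from the closed form sum (O - E)^2 / E
chisq_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(stat = stat, p = pchisq(stat, df = df, lower.tail = FALSE))
}

# small deterministic expression matrix
toy_expression <- function(n = 12, p = 6, seed = 42) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n * p), n, p,
                           dimnames = list(paste0("S", 1:n),
                                           paste0("g", 1:p))))
}

write_toy_gmt <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}
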