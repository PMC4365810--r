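# Per-PC competitive gene set testing: Fisher-transformed gene-PC
# correlations as the gene-level statistic, correlation-adjusted
# standardized mean difference as the set statistic, two-sided t-test.

#' Gene-level association statistics for one PC
#'
#' Computes, for every genomic variable, the Fisher-transformed Pearson
#' correlation with a PC score vector, scaled to an approximate z-score:
#' `z_j = sqrt(n - 3) * atanh(r_j)`.
#'
#' @param x_std standardized matrix (see [standardize()]).
#' @param pc_scores numeric length-`n` score vector for one PC.
#' @param n sample size; defaults to `nrow(x_std)`. Must be at least 4 so
#'   the Fisher scale factor is positive.
#' @return Numeric length-`p` vector of z statistics.
#'
#' @details Correlations are clipped to `1 - 1e-12` in absolute value
#'   before the `atanh` so genes perfectly aligned with a PC do not map to
#'   infinity.
#' @export
gene_level_statistics <- function(x_std, pc_scores, n = nrow(x_std)) {
  if (n < 4L) stop("gene-level statistics need n >= 4")
  if (stats::sd(pc_scores) == 0) stop("PC score vector is constant")
  r <- as.vector(stats::cor(x_std, pc_scores))
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  sqrt(n - 3) * atanh(r)
}

# p x q matrix of gene-level z statistics for all q PCs at once
gene_pc_statistics <- function(x_std, scores, q) {
  n <- nrow(x_std)
  if (n < 4L) stop("gene-level statistics need n >= 4")
  r <- stats::cor(x_std, scores[, seq_len(q), drop = FALSE])
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  sqrt(n - 3) * atanh(r)
}

#' Mean pairwise correlation among gene set members
#'
#' Average of the `m * (m - 1) / 2` distinct pairwise Pearson correlations
#' among the member columns; this is the quantity that inflates the
#' variance of a mean of `m` correlated gene-level statistics.
#'
#' @param x_std standardized matrix.
#' @param member_index integer or logical index of the `m >= 2` member
#'   columns.
#' @return The mean pairwise correlation, a scalar in `[-1, 1]`.
#' @export
mean_pairwise_correlation <- function(x_std, member_index) {
  cols <- x_std[, member_index, drop = FALSE]
  m <- ncol(cols)
  if (m < 2L) stop("at least 2 member variables are required")
  cc <- stats::cor(cols)
  mean(cc[upper.tri(cc)])
}

#' Competitive gene set test for one PC
#'
#' Correlation-adjusted standardized mean difference between the
#' gene-level statistics of set members and non-members, tested two-sided
#' against a t distribution with `p - 2` degrees of freedom. The member
#' group's variance contribution is inflated by `VIF = 1 + (m - 1) *
#' rho_bar` to account for inter-gene correlation, which is what keeps the
#' competitive test calibrated when set members are co-expressed.
#'
#' @param stats_values numeric length-`p` vector of gene-level statistics
#'   (see [gene_level_statistics()]).
#' @param membership_row binary length-`p` vector; `1` marks set members.
#' @param rho_bar mean pairwise correlation among members (see
#'   [mean_pairwise_correlation()]). Negative values are floored at 0: a
#'   negative average correlation would deflate the variance and
#'   anti-conservatively inflate the statistic.
#' @param p number of variables; defaults to `length(stats_values)`.
#' @return A list with `t_stat`, `df`, `pvalue`, `vif` and `set_size`.
#'
#' @details The statistic is
#'   `t = (mean_members - mean_rest) / (sd_pooled * sqrt(VIF/m + 1/(p - m)))`
#'   with the usual pooled standard deviation over both groups.
#' @export
set_test <- function(stats_values, membership_row, rho_bar,
                     p = length(stats_values)) {
  mem <- as.logical(membership_row)
  m <- sum(mem)
  if (m == 0L || m == p)
    stop("set size must satisfy 1 <= m < p (got m = ", m, ", p = ", p, ")")
  vif <- 1 + (m - 1) * max(rho_bar, 0)
  z1 <- stats_values[mem]
  z2 <- stats_values[!mem]
  v1 <- if (m > 1L) stats::var(z1) else 0
  v2 <- if (p - m > 1L) stats::var(z2) else 0
  sd_pooled <- sqrt(((m - 1) * v1 + (p - m - 1) * v2) / (p - 2))
  if (sd_pooled == 0) stop("pooled standard deviation is zero")
  t_stat <- (mean(z1) - mean(z2)) / (sd_pooled * sqrt(vif / m + 1 / (p - m)))
  df <- p - 2L
  list(t_stat = t_stat, df = df,
       pvalue = 2 * stats::pt(-abs(t_stat), df = df),
       vif = vif, set_size = m)
}

#' Per-PC gene set p-value matrix
#'
#' Runs the competitive set test for every gene set against each of the
#' first `q` PCs. The mean pairwise member correlation is computed once per
#' set (it does not depend on the PC under test).
#'
#' @param x_std standardized matrix.
#' @param spec a [compute_spectra()] result for `x_std`.
#' @param sets a [gene_set_collection()] aligned to the columns of `x_std`.
#' @param q number of PCs to test, `q <= spec$rank`.
#' @return An `f x q` matrix of two-sided p-values, rows named by set,
#'   columns `PC1..PCq`.
#' @export
pcgse_matrix <- function(x_std, spec, sets, q) {
  stopifnot(inherits(spec, "spectral_decomposition"),
            inherits(sets, "gene_set_collection"))
  if (q > spec$rank) stop("q = ", q, " exceeds rank ", spec$rank)
  p <- ncol(x_std)
  z <- gene_pc_statistics(x_std, spec$scores, q)
  f <- nrow(sets$membership)
  out <- matrix(NA_real_, f, q,
                dimnames = list(sets$set_names, paste0("PC", seq_len(q))))
  for (j in seq_len(f)) {
    mem <- sets$membership[j, ] == 1L
    m <- sum(mem)
    if (m == 0L || m == p)
      stop("set '", sets$set_names[j], "' has degenerate size ", m)
    rho <- if (m >= 2L) mean_pairwise_correlation(x_std, mem) else 0
    vif <- 1 + (m - 1) * max(rho, 0)
    z1 <- z[mem, , drop = FALSE]
    z2 <- z[!mem, , drop = FALSE]
    mean1 <- colMeans(z1)
    mean2 <- colMeans(z2)
    var1 <- if (m > 1L) apply(z1, 2L, stats::var) else rep(0, q)
    var2 <- if (p - m > 1L) apply(z2, 2L, stats::var) else rep(0, q)
    sd_pooled <- sqrt(((m - 1) * var1 + (p - m - 1) * var2) / (p - 2))
    t_stat <- (mean1 - mean2) / (sd_pooled * sqrt(vif / m + 1 / (p - m)))
    out[j, ] <- 2 * stats::pt(-abs(t_stat), df = p - 2L)
  }
  out
}
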