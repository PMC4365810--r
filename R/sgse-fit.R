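#' Principal component weights for p-value combination
#'
#' Weights used by the weighted Z-method in [sgse()]. The `"variance"`
#' scheme sets `w_i = lambda_i`, so every PC contributes in proportion to
#' the variance it carries. The `"tw_scaled_variance"` scheme sets
#' `w_i = F_TW(tw_i) * lambda_i`: the PC variance scaled by the lower-tail
#' Tracy-Widom probability of its eigenvalue, which leaves highly
#' significant PCs at essentially their variance weight while driving the
#' weight of noise-level PCs towards zero.
#'
#' @param spec a [compute_spectra()] result.
#' @param sig a [pc_significance()] result for the same decomposition
#'   (only needed for the Tracy-Widom scheme).
#' @param scheme `"tw_scaled_variance"` (default) or `"variance"`.
#' @param q number of leading PCs to weight.
#' @return Numeric length-`q` vector of nonnegative weights.
#' @export
pc_weights <- function(spec, sig = NULL,
                       scheme = c("tw_scaled_variance", "variance"),
                       q = spec$rank) {
  scheme <- match.arg(scheme)
  if (q < 1L || q > spec$rank) stop("'q' must be in [1, rank]")
  lam <- spec$eigenvalues[seq_len(q)]
  w <- switch(scheme,
    variance = lam,
    tw_scaled_variance = {
      if (is.null(sig)) stop("the Tracy-Widom scheme needs 'sig'")
      sig$lower_cdf[seq_len(q)] * lam
    })
  if (all(w == 0))
    stop("all PC weights are zero; the combination is degenerate")
  w
}

#' Combine p-values with the weighted Z-method
#'
#' Stouffer-style combination of independent one-sided evidence:
#' `Z = sum(w_i * qnorm(1 - p_i)) / sqrt(sum(w_i^2))`, with the combined
#' p-value `1 - pnorm(Z)`. With a single component the input p-value is
#' returned unchanged; with all p-values at 0.5 the result is 0.5 for any
#' weights.
#'
#' @param pvalues numeric vector of p-values in `(0, 1)`.
#' @param weights numeric vector of nonnegative weights, same length, not
#'   all zero.
#' @return A list with `z` and `combined_p`.
#'
#' @details p-values are clipped to `[1e-15, 1 - 1e-15]` before the normal
#'   quantile transform; this bounds `Z` when an input p-value underflows
#'   to 0 and is the only deviation from the literal formula.
#' @export
weighted_z_combine <- function(pvalues, weights) {
  if (length(pvalues) == 0L) stop("no p-values to combine")
  if (length(weights) != length(pvalues))
    stop("'weights' and 'pvalues' must have the same length")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("all weights are zero")
  eps <- 1e-15
  pv <- pmin(pmax(pvalues, eps), 1 - eps)
  z <- sum(weights * stats::qnorm(pv, lower.tail = FALSE)) /
    sqrt(sum(weights^2))
  list(z = z, combined_p = stats::pnorm(z, lower.tail = FALSE))
}

#' Spectral gene set enrichment
#'
#' Tests the association between each gene set and the full
#' principal-component structure (the "spectra") of a genomic data matrix,
#' without any phenotype variable. The data are standardized, the PCA
#' solution is computed by SVD, each retained PC receives a competitive
#' per-PC gene set p-value (correlation-adjusted standardized mean
#' difference on Fisher-transformed gene-PC correlations), and the per-PC
#' p-values are combined across PCs with the weighted Z-method using
#' PC-variance or Tracy-Widom-scaled variance weights.
#'
#' @param x an [expression_matrix()] or a plain numeric matrix with
#'   samples in rows and variables in columns.
#' @param gene_sets a [gene_set_collection()]; its variable universe must
#'   cover the variables of `x` (alignment is by identifier).
#' @param selection a [pc_selection()], or one of the mode strings
#'   `"all_nonzero"` (default), `"significant"`, `"fixed"`.
#' @param alpha,q_star convenience arguments forwarded to [pc_selection()]
#'   when `selection` is given as a string.
#' @param weights weight scheme, `"tw_scaled_variance"` (default) or
#'   `"variance"`; see [pc_weights()].
#'
#' @return An object of class `"sgse"`: a list with
#'   \describe{
#'     \item{combined_pvalues}{named length-`f` vector, one p-value per
#'       gene set (Eq. `1 - pnorm(Z)`).}
#'     \item{combined_z}{the weighted Z statistics.}
#'     \item{per_pc_pvalues}{`f x q` matrix of per-PC competitive
#'       p-values.}
#'     \item{pc_weights}{the length-`q` weight vector used.}
#'     \item{q, weight_scheme}{number of PCs combined and the scheme.}
#'     \item{spectra, pc_significance}{the underlying decomposition and
#'       Tracy-Widom significance objects.}
#'   }
#'   The fit is fully deterministic: running twice on identical input
#'   yields identical results.
#'
#' @examples
#' set.seed(1)
#' x <- simulate_dataset(covariance_model("single_factor"), n = 50, seed = 7)
#' sets <- make_gene_sets(p = 200, n_sets = 10, set_size = 20)
#' fit <- sgse(x, sets)
#' fit
#' head(summary(fit))
#' @export
sgse <- function(x, gene_sets,
                 selection = c("all_nonzero", "significant", "fixed"),
                 alpha = 0.05, q_star = NULL,
                 weights = c("tw_scaled_variance", "variance")) {
  weights <- match.arg(weights)
  if (!inherits(selection, "pc_selection"))
    selection <- pc_selection(match.arg(selection), alpha = alpha,
                              q_star = q_star)
  if (!inherits(x, "expression_matrix")) x <- expression_matrix(x)
  gene_sets <- align_gene_sets(gene_sets, x$variable_ids)
  x_std <- standardize(x)
  spec <- compute_spectra(x_std)
  sig <- pc_significance(spec)
  q <- select_pcs(spec, sig, selection)
  per_pc <- pcgse_matrix(x_std, spec, gene_sets, q)
  w <- pc_weights(spec, sig, scheme = weights, q = q)
  comb <- apply(per_pc, 1L, weighted_z_combine, weights = w)
  z <- vapply(comb, `[[`, numeric(1L), "z")
  pv <- vapply(comb, `[[`, numeric(1L), "combined_p")
  structure(list(combined_pvalues = pv, combined_z = z,
                 per_pc_pvalues = per_pc, pc_weights = w, q = q,
                 weight_scheme = weights, selection = selection,
                 spectra = spec, pc_significance = sig,
                 set_names = gene_sets$set_names, call = match.call()),
            class = "sgse")
}

#' @export
print.sgse <- function(x, ...) {
  cat("Spectral gene set enrichment\n")
  cat("  ", length(x$combined_pvalues), " gene sets, ", x$q,
      " PCs combined, ", x$weight_scheme, " weights\n", sep = "")
  cat("  gene sets with p < 0.05: ", sum(x$combined_pvalues < 0.05), "\n",
      sep = "")
  invisible(x)
}

#' Summarize a spectral enrichment fit
#'
#' @param object an [sgse()] fit.
#' @param adjust multiple-testing adjustment for the optional `padj`
#'   column (any method of [stats::p.adjust()]; default `"BH"`, use
#'   `"none"` to omit adjustment).
#' @param ... unused.
#' @return A data frame with one row per gene set, ordered by combined
#'   p-value: `set`, `p`, `z`, `padj`.
#' @export
summary.sgse <- function(object, adjust = "BH", ...) {
  out <- data.frame(set = names(object$combined_pvalues),
                    p = unname(object$combined_pvalues),
                    z = unname(object$combined_z),
                    padj = stats::p.adjust(object$combined_pvalues,
                                           method = adjust),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}

#' @export
as.data.frame.sgse <- function(x, ...) summary.sgse(x, ...)

#' QQ plot of combined enrichment p-values
#'
#' Plots the sorted combined p-values against uniform quantiles. Under a
#' global null the points follow the diagonal; points above the diagonal
#' at the low end indicate a conservative test, points below an
#' anti-conservative one.
#'
#' @param x an [sgse()] fit.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.sgse <- function(x, ...) {
  qq <- qq_summary(x$combined_pvalues)
  graphics::plot(qq$uniform, qq$empirical, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "uniform quantile", ylab = "empirical p-value",
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write an enrichment result table
#'
#' Writes one row per gene set (name, combined p-value, combined Z, number
#' of PCs, weight scheme) as a tab-delimited file, and optionally the full
#' per-PC p-value matrix as a companion file with one column per PC.
#' Values are written with full precision (15 significant digits) so a
#' round trip preserves them.
#'
#' @param result an [sgse()] fit.
#' @param path output file path.
#' @param per_pc_path optional path for the `f x q` per-PC p-value matrix.
#' @return Invisibly, `path`.
#' @export
write_enrichment_result <- function(result, path, per_pc_path = NULL) {
  stopifnot(inherits(result, "sgse"))
  tab <- data.frame(set = names(result$combined_pvalues),
                    combined_pvalue = format(result$combined_pvalues,
                                             digits = 15L, trim = TRUE),
                    combined_z = format(result$combined_z, digits = 15L,
                                        trim = TRUE),
                    q = result$q,
                    weight_scheme = result$weight_scheme,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(per_pc_path)) {
    m <- result$per_pc_pvalues
    ptab <- data.frame(set = rownames(m),
                       apply(m, 2L, format, digits = 15L, trim = TRUE),
                       stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(ptab, per_pc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
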