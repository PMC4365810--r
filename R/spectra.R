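#' Center and standardize an expression matrix
#'
#' Mean-centers every column and scales it to unit sample standard
#' deviation (denominator `n - 1`). All spectral computations in this
#' package operate on the standardized matrix, so principal components are
#' those of the sample correlation matrix; PCs are otherwise not invariant
#' under per-gene rescaling of the data.
#'
#' @param x an [expression_matrix()] or a plain numeric matrix
#'   (samples in rows).
#' @return A numeric `n x p` matrix with column means 0 and column sds 1.
#' @examples
#' standardize(matrix(c(1, 2, 3, 5, 5, 8), 3, 2))
#' @export
standardize <- function(x) {
  v <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (nrow(v) < 3L) stop("standardization needs at least 3 samples")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(v)
    bad <- if (is.null(nm)) which(sds == 0) else nm[sds == 0]
    stop("constant column(s) cannot be standardized: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  out <- scale(v, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Spectral decomposition of a standardized data matrix
#'
#' Computes the PCA solution via the singular value decomposition of the
#' standardized matrix. Eigenvalues are the squared singular values divided
#' by `n - 1`, i.e. the eigenvalues of the sample correlation matrix
#' `S = crossprod(x_std) / (n - 1)`; loading vectors are the right singular
#' vectors; PC scores are the data projected onto the loadings.
#'
#' @param x_std standardized matrix, as returned by [standardize()].
#' @return An object of class `"spectral_decomposition"`: a list with
#'   `eigenvalues` (nonincreasing, length `r`), `loadings` (`p x r`,
#'   orthonormal columns), `scores` (`n x r`), `rank` (`r`), `n`, `p`.
#'
#' @details Components with eigenvalue below `1e-12 * lambda_1` are
#'   truncated, so `rank` equals the number of PCs with non-zero variance
#'   under floating point (`r <= min(n - 1, p)` after centering). Each
#'   loading vector is oriented so that its largest-magnitude element is
#'   positive (ties broken by lowest index); downstream enrichment
#'   statistics are sign-invariant, the convention only makes output
#'   deterministic.
#' @export
compute_spectra <- function(x_std) {
  x_std <- as.matrix(x_std)
  n <- nrow(x_std)
  p <- ncol(x_std)
  sv <- svd(x_std)
  lambda <- sv$d^2 / (n - 1)
  keep <- lambda > 1e-12 * lambda[1L]
  r <- sum(keep)
  lambda <- lambda[keep]
  loadings <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude loading element positive
  for (j in seq_len(r)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- x_std %*% loadings
  rownames(loadings) <- colnames(x_std)
  rownames(scores) <- rownames(x_std)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(r))
  structure(list(eigenvalues = lambda, loadings = loadings, scores = scores,
                 rank = r, n = n, p = p),
            class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat("Spectral decomposition: n = ", x$n, ", p = ", x$p, ", rank = ",
      x$rank, "\n", sep = "")
  cat("Leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5L), 4L), collapse = ", "),
      "\n")
  invisible(x)
}
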