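# Tracy-Widom (order 1) moments and the moment-matched shifted-Gamma
# approximation (Chiani-style). Constants are frozen from the published
# TW1 mean/variance/skewness; a regression test checks the resulting CDF
# against an independent Painleve II oracle.
TW1_MEAN <- -1.2065335745820
TW1_VAR <- 1.607781034581
TW1_SKEW <- 0.29346452408
TW1_GAMMA_SHAPE <- 46.446048843878  # 4 / skew^2
TW1_GAMMA_SCALE <- 0.18605402228279  # sqrt(var / shape)
TW1_GAMMA_SHIFT <- 9.8480077811288  # shape * scale - mean

#' Tracy-Widom order-1 cumulative distribution function
#'
#' CDF of the Tracy-Widom law of order 1, the limiting distribution of the
#' rescaled largest eigenvalue of a white Wishart matrix. Computed with the
#' shifted-Gamma approximation whose shape, scale and shift are moment
#' matched to the TW1 mean, variance and skewness; the approximation is
#' accurate to about 1e-3 absolute over the whole support and gives
#' smooth coverage of both tails.
#'
#' @param q numeric vector of quantiles.
#' @param lower.tail if `TRUE` (default) returns `P(TW1 <= q)`, otherwise
#'   the upper tail.
#' @return Probabilities in `[0, 1]`, monotone in `q`.
#' @examples
#' ptw1(c(-2, 0, 2))
#' @export
ptw1 <- function(q, lower.tail = TRUE) {
  stats::pgamma(q + TW1_GAMMA_SHIFT, shape = TW1_GAMMA_SHAPE,
                scale = TW1_GAMMA_SCALE, lower.tail = lower.tail)
}

#' Rescale an eigenvalue to a Tracy-Widom statistic
#'
#' Centers and scales the `i`-th sample eigenvalue so that, under a null of
#' uncorrelated multivariate normal data, it is approximately Tracy-Widom
#' (order 1) distributed. The `i`-th eigenvalue is compared against the
#' null largest-eigenvalue distribution of the remaining
#' `p_eff = p - i + 1` dimensions, which yields a conservative significance
#' for trailing PCs under a spiked alternative.
#'
#' @param lambda_i sample eigenvalue (of the correlation matrix, `n - 1`
#'   denominator).
#' @param index_i 1-based eigenvalue index.
#' @param n,p sample size and number of variables.
#' @return The Tracy-Widom statistic `(lambda_i - mu) / sigma`.
#'
#' @details The centering and scale are
#'   `mu = (sqrt(n - 1) + sqrt(p_eff))^2 / n` and
#'   `sigma = ((sqrt(n - 1) + sqrt(p_eff)) / n) *
#'   (1/sqrt(n - 1) + 1/sqrt(p_eff))^(1/3)`.
#'   When `p_eff > n` the roles of `n` and `p_eff` are exchanged inside the
#'   square roots (the Wishart distribution of the dual matrix has the same
#'   non-zero spectrum) while the `1/n` normalization of the sample
#'   eigenvalue scale is kept, so the statistic is continuous across
#'   `p_eff = n`.
#' @export
tw_rescale <- function(lambda_i, index_i, n, p) {
  if (n < 2L) stop("'n' must be at least 2")
  if (index_i < 1L || index_i > min(n - 1L, p))
    stop("'index_i' must be in [1, min(n - 1, p)]")
  p_eff <- p - index_i + 1
  if (p_eff < 1L) stop("effective dimension p - i + 1 must be >= 1")
  # larger of the two dimensions goes inside sqrt(d1 - 1)
  d1 <- max(n, p_eff)
  d2 <- min(n, p_eff)
  s <- sqrt(d1 - 1) + sqrt(d2)
  mu <- s^2 / n
  sigma <- (s / n) * (1 / sqrt(d1 - 1) + 1 / sqrt(d2))^(1 / 3)
  (lambda_i - mu) / sigma
}

#' Tracy-Widom significance of the principal components
#'
#' Assigns every retained PC a Tracy-Widom statistic and the two tails of
#' its null distribution: the upper-tail p-value `1 - F_TW(tw_i)` measures
#' how unlikely an eigenvalue this large is under uncorrelated MVN data,
#' and the lower-tail CDF value `F_TW(tw_i)` is the scaling factor used by
#' the Tracy-Widom weight scheme of [sgse()].
#'
#' @param spec a [compute_spectra()] result.
#' @return An object of class `"pc_significance"`: a list with `tw_stats`,
#'   `upper_pvalues` and `lower_cdf`, each of length `spec$rank`. The two
#'   tails sum to 1 by construction.
#' @export
pc_significance <- function(spec) {
  stopifnot(inherits(spec, "spectral_decomposition"))
  tw <- vapply(seq_len(spec$rank), function(i)
    tw_rescale(spec$eigenvalues[i], i, spec$n, spec$p), numeric(1L))
  lower <- ptw1(tw)
  structure(list(tw_stats = tw, upper_pvalues = 1 - lower,
                 lower_cdf = lower),
            class = "pc_significance")
}

#' @export
print.pc_significance <- function(x, ...) {
  k <- min(5L, length(x$tw_stats))
  cat("Tracy-Widom PC significance (first ", k, " of ", length(x$tw_stats),
      " PCs):\n", sep = "")
  print(data.frame(tw = signif(x$tw_stats[seq_len(k)], 4L),
                   p_upper = signif(x$upper_pvalues[seq_len(k)], 4L)))
  invisible(x)
}

#' Specify how many principal components to use
#'
#' Three policies are supported for choosing `q`, the number of PCs
#' representing the spectra: all PCs with non-zero variance (the default
#' used throughout the simulation studies), all PCs significant at level
#' `alpha` under the Tracy-Widom null, or a fixed number `q_star`.
#'
#' @param mode `"all_nonzero"`, `"significant"` or `"fixed"`.
#' @param alpha significance level in (0, 1); used when
#'   `mode = "significant"`.
#' @param q_star positive integer; used when `mode = "fixed"`. It may not
#'   exceed the number of PCs with non-zero variance.
#' @return An object of class `"pc_selection"`.
#' @seealso [select_pcs()]
#' @export
pc_selection <- function(mode = c("all_nonzero", "significant", "fixed"),
                         alpha = 0.05, q_star = NULL) {
  mode <- match.arg(mode)
  if (mode == "significant" &&
      (!is.numeric(alpha) || alpha <= 0 || alpha >= 1))
    stop("'alpha' must be in (0, 1)")
  if (mode == "fixed") {
    if (is.null(q_star) || q_star < 1L)
      stop("mode 'fixed' needs a positive 'q_star'")
    q_star <- as.integer(q_star)
  }
  structure(list(mode = mode, alpha = alpha, q_star = q_star),
            class = "pc_selection")
}

#' Resolve the number of PCs for a given decomposition
#'
#' @param spec a [compute_spectra()] result.
#' @param sig a [pc_significance()] result for the same decomposition.
#' @param selection a [pc_selection()].
#' @return Integer `q`, `1 <= q <= spec$rank`.
#'
#' @details With `mode = "significant"`, zero significant PCs is an error
#'   (the combination would be empty); switch to `"all_nonzero"` or
#'   `"fixed"` in that case. With `mode = "fixed"`, `q_star` larger than
#'   the rank is an error, not a silent clamp.
#' @export
select_pcs <- function(spec, sig, selection) {
  stopifnot(inherits(spec, "spectral_decomposition"),
            inherits(selection, "pc_selection"))
  switch(selection$mode,
    all_nonzero = spec$rank,
    significant = {
      q <- sum(sig$upper_pvalues < selection$alpha)
      if (q == 0L)
        stop("no PC is significant at alpha = ", selection$alpha,
             "; use mode 'all_nonzero' or 'fixed' instead")
      q
    },
    fixed = {
      if (selection$q_star > spec$rank)
        stop("q_star = ", selection$q_star, " exceeds the number of PCs ",
             "with non-zero variance (", spec$rank, ")")
      selection$q_star
    })
}
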