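# Spiked-covariance simulation harness: identity, single-factor and
# two-factor MVN population models, block gene sets, and replicated
# type-I-error / power studies for the enrichment methods.

#' Population covariance model for simulated expression data
#'
#' Defines the population covariance `Sigma` of a `p`-dimensional MVN
#' expression vector as a low-rank factor part plus isotropic noise:
#' `Sigma = sum_k lambda_k * a_k a_k' + lambda_d * I`.
#'
#' Three designs are supported:
#' \describe{
#'   \item{`identity`}{`Sigma = I`; no structure, a true global null.}
#'   \item{`single_factor`}{one factor with variance 4 loading
#'     `sqrt(0.05)` on variables 1-20 (unit-norm loading vector); the
#'     first block gene set is associated with PC 1. Member variables
#'     have population variance 1.2 and pairwise correlation 1/6.}
#'   \item{`two_factor`}{factors with variances 4 and 3 loading
#'     `sqrt(0.1)` on variables 1-10 and 11-20 respectively (orthonormal
#'     loadings); the first gene set splits across PCs 1 and 2.}
#' }
#'
#' @param design `"identity"`, `"single_factor"` or `"two_factor"`.
#' @param p number of variables; default 200 (the loadings above assume
#'   `p >= 20`).
#' @param noise_variance isotropic noise variance `lambda_d`; default 1.
#' @return An object of class `"covariance_model"`: a list with `design`,
#'   `p`, `factor_variances`, `loadings` (`p x k` matrix or `NULL`) and
#'   `noise_variance`.
#' @export
covariance_model <- function(design = c("identity", "single_factor",
                                        "two_factor"),
                             p = 200L, noise_variance = 1) {
  design <- match.arg(design)
  p <- as.integer(p)
  if (design != "identity" && p < 20L)
    stop("factor designs need p >= 20")
  loadings <- NULL
  factor_variances <- numeric(0L)
  if (design == "single_factor") {
    a1 <- c(rep(sqrt(0.05), 20L), rep(0, p - 20L))
    loadings <- matrix(a1, ncol = 1L)
    factor_variances <- 4
  } else if (design == "two_factor") {
    a1 <- c(rep(sqrt(0.1), 10L), rep(0, p - 10L))
    a2 <- c(rep(0, 10L), rep(sqrt(0.1), 10L), rep(0, p - 20L))
    loadings <- cbind(a1, a2)
    factor_variances <- c(4, 3)
  }
  structure(list(design = design, p = p,
                 factor_variances = factor_variances,
                 loadings = loadings, noise_variance = noise_variance),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("Covariance model '", x$design, "': p = ", x$p, sep = "")
  if (length(x$factor_variances))
    cat(", factor variances ", paste(x$factor_variances, collapse = ", "),
        sep = "")
  cat(", noise variance ", x$noise_variance, "\n", sep = "")
  invisible(x)
}

#' Population covariance matrix of a model
#'
#' @param model a [covariance_model()].
#' @return The `p x p` matrix `Sigma`.
#' @export
population_covariance <- function(model) {
  stopifnot(inherits(model, "covariance_model"))
  sigma <- diag(model$noise_variance, model$p)
  if (length(model$factor_variances))
    sigma <- sigma + model$loadings %*%
      (model$factor_variances * t(model$loadings))
  sigma
}

#' Simulate one MVN expression dataset
#'
#' Draws `n` i.i.d. observations from `MVN(0, Sigma)` using the factor
#' construction `x = sum_k sqrt(lambda_k) * a_k * f_k + sqrt(lambda_d) *
#' eps` with standard normal factor scores `f_k` and noise `eps`, which is
#' exactly equivalent in distribution to sampling with a full `p x p`
#' Cholesky factor.
#'
#' @param model a [covariance_model()].
#' @param n number of observations; default 50. Must be at least 4.
#' @param seed integer seed; a fixed seed reproduces the dataset exactly.
#' @return An [expression_matrix()] with samples `S1..Sn` and variables
#'   `V1..Vp`.
#' @export
simulate_dataset <- function(model, n = 50L, seed = 1L) {
  stopifnot(inherits(model, "covariance_model"))
  if (n < 4L) stop("'n' must be at least 4")
  set.seed(seed)
  k <- length(model$factor_variances)
  x <- sqrt(model$noise_variance) * matrix(stats::rnorm(n * model$p), n,
                                           model$p)
  if (k > 0L) {
    f <- matrix(stats::rnorm(n * k), n, k)
    x <- x + f %*% (sqrt(model$factor_variances) * t(model$loadings))
  }
  expression_matrix(x, sample_ids = paste0("S", seq_len(n)),
                    variable_ids = paste0("V", seq_len(model$p)))
}

#' Disjoint block gene sets
#'
#' Builds `n_sets` disjoint gene sets of equal size over contiguous blocks
#' of variables: set `j` contains variables `(j-1)*set_size + 1` through
#' `j*set_size`. With the factor designs of [covariance_model()] the first
#' set therefore covers the factor support exactly.
#'
#' @param p number of variables in the universe.
#' @param n_sets number of sets; default 10.
#' @param set_size members per set; default 20.
#' @return A [gene_set_collection()] over variables `V1..Vp`.
#' @export
make_gene_sets <- function(p, n_sets = 10L, set_size = 20L) {
  if (n_sets * set_size > p)
    stop("n_sets * set_size = ", n_sets * set_size, " exceeds p = ", p)
  ids <- paste0("V", seq_len(p))
  members <- lapply(seq_len(n_sets), function(j)
    ids[((j - 1L) * set_size + 1L):(j * set_size)])
  names(members) <- paste0("set", seq_len(n_sets))
  gene_set_collection(members, variable_ids = ids)
}

#' Replicated simulation study of the enrichment methods
#'
#' Simulates `n_reps` datasets under one covariance design, runs spectral
#' enrichment with both weight schemes and the cluster-based benchmark
#' (fixed `k`) on every replicate, and estimates rejection rates at level
#' `alpha`. Under the identity design the headline rate pools all sets and
#' replicates (under the null all sets are exchangeable, so pooling only
#' shrinks the Monte-Carlo error); under the factor designs the headline
#' rate is the empirical power for gene set 1, whose members carry the
#' factor structure.
#'
#' @param design `"identity"`, `"single_factor"` or `"two_factor"`.
#' @param n_reps number of replicate datasets; default 1000.
#' @param n,p samples and variables per dataset; defaults 50 and 200.
#' @param alpha rejection level; default 0.05.
#' @param methods subset of `c("sgse_variance", "sgse_tw", "cluster")`.
#' @param n_sets,set_size gene set layout; defaults 10 disjoint sets of 20.
#' @param k,restarts cluster-benchmark settings; defaults `k = 2`, 5
#'   restarts.
#' @param seed master seed. Per-replicate seeds for data generation and
#'   clustering are drawn once from the master seed, so identical master
#'   seeds give identical studies and any single replicate can be redone
#'   in isolation.
#' @return An object of class `"sgse_simulation"`: a list with
#'   \describe{
#'     \item{pvalues}{per method, an `n_reps x n_sets` matrix of combined
#'       p-values.}
#'     \item{rejection}{data frame with per-method set-1 rejection rate,
#'       pooled all-sets rate, the headline `rate` for the design, and its
#'       binomial standard error.}
#'     \item{design, alpha, n_reps, n, p, seed}{the study conditions.}
#'   }
#' @examples
#' \donttest{
#' study <- run_simulation_study("single_factor", n_reps = 50, seed = 11)
#' study$rejection
#' }
#' @export
run_simulation_study <- function(design = c("identity", "single_factor",
                                            "two_factor"),
                                 n_reps = 1000L, n = 50L, p = 200L,
                                 alpha = 0.05,
                                 methods = c("sgse_variance", "sgse_tw",
                                             "cluster"),
                                 n_sets = 10L, set_size = 20L, k = 2L,
                                 restarts = 5L, seed = 1L) {
  design <- match.arg(design)
  methods <- match.arg(methods, several.ok = TRUE)
  model <- covariance_model(design, p = p)
  sets <- make_gene_sets(p, n_sets = n_sets, set_size = set_size)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2147483646L, 2L * n_reps), n_reps, 2L)
  pvals <- lapply(methods, function(m)
    matrix(NA_real_, n_reps, n_sets,
           dimnames = list(NULL, sets$set_names)))
  names(pvals) <- methods
  want_sgse <- any(c("sgse_variance", "sgse_tw") %in% methods)
  for (r in seq_len(n_reps)) {
    x <- simulate_dataset(model, n = n, seed = rep_seeds[r, 1L])
    if (want_sgse) {
      x_std <- standardize(x)
      spec <- compute_spectra(x_std)
      sig <- pc_significance(spec)
      q <- spec$rank
      per_pc <- pcgse_matrix(x_std, spec, sets, q)
      if ("sgse_variance" %in% methods) {
        w <- pc_weights(spec, sig, "variance", q)
        pvals$sgse_variance[r, ] <- apply(per_pc, 1L, function(pv)
          weighted_z_combine(pv, w)$combined_p)
      }
      if ("sgse_tw" %in% methods) {
        w <- pc_weights(spec, sig, "tw_scaled_variance", q)
        pvals$sgse_tw[r, ] <- apply(per_pc, 1L, function(pv)
          weighted_z_combine(pv, w)$combined_p)
      }
    }
    if ("cluster" %in% methods) {
      ce <- cluster_enrich(x, sets, k = k, restarts = restarts,
                           seed = rep_seeds[r, 2L])
      pvals$cluster[r, ] <- ce$pvalues
    }
  }
  set1 <- vapply(pvals, function(m) mean(m[, 1L] < alpha), numeric(1L))
  pooled <- vapply(pvals, function(m) mean(m < alpha), numeric(1L))
  headline <- if (design == "identity") pooled else set1
  n_trials <- if (design == "identity") n_reps * n_sets else n_reps
  rejection <- data.frame(method = methods,
                          set1_rate = unname(set1),
                          pooled_rate = unname(pooled),
                          rate = unname(headline),
                          se = sqrt(pmax(headline * (1 - headline), 0) /
                                    n_trials),
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(pvalues = pvals, rejection = rejection, design = design,
                 alpha = alpha, n_reps = n_reps, n = n, p = p,
                 seed = seed),
            class = "sgse_simulation")
}

#' @export
print.sgse_simulation <- function(x, ...) {
  cat("Simulation study: ", x$design, " design, ", x$n_reps,
      " replicates of n = ", x$n, ", p = ", x$p, "\n", sep = "")
  cat(if (x$design == "identity") "Type-I error" else "Power (set 1)",
      " at alpha = ", x$alpha, ":\n", sep = "")
  tab <- x$rejection
  tab$rate <- signif(tab$rate, 3L)
  tab$se <- signif(tab$se, 2L)
  print(tab[, c("method", "rate", "se")], row.names = FALSE)
  invisible(x)
}

#' Quantile-quantile summary of a p-value sample
#'
#' Pairs the sorted p-values with uniform plotting positions `i / (N + 1)`
#' for export or plotting; under a uniform null the two columns agree up
#' to sampling noise.
#'
#' @param pvalues numeric vector of p-values.
#' @return A data frame with columns `uniform` and `empirical`.
#' @export
qq_summary <- function(pvalues) {
  if (length(pvalues) == 0L) stop("no p-values given")
  nn <- length(pvalues)
  data.frame(uniform = seq_len(nn) / (nn + 1),
             empirical = sort(pvalues))
}
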