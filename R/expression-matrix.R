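#' Construct an expression matrix
#'
#' Bundles an `n x p` numeric data matrix (samples/conditions in rows,
#' genomic variables in columns) with its sample and variable identifiers.
#' This is the data container consumed by [sgse()], [cluster_enrich()] and
#' the spectral functions. Any transformation (log, variance stabilization)
#' is assumed to have been applied already; missing values must have been
#' imputed or removed beforehand.
#'
#' @param values numeric matrix, `n` rows by `p` columns, no missing values.
#' @param sample_ids character vector of `n` unique sample labels. Defaults
#'   to the row names of `values`.
#' @param variable_ids character vector of `p` unique variable (gene/probe)
#'   labels. Defaults to the column names of `values`.
#'
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values`, `sample_ids` and `variable_ids`.
#'
#' @details At least 3 samples and 2 variables are required: the per-gene
#'   Fisher transform uses a `sqrt(n - 3)` scale factor, and the spectral
#'   decomposition needs a nontrivial column space. Constant columns are
#'   rejected at standardization time, not here, so that subsetting remains
#'   cheap.
#'
#' @examples
#' x <- expression_matrix(matrix(rnorm(30), 6, 5))
#' x
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              variable_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be a numeric matrix")
  n <- nrow(values)
  p <- ncol(values)
  if (n < 3L || p < 2L)
    stop("an expression matrix needs at least 3 samples and 2 variables (got ",
         n, " x ", p, ")")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    stop("missing values are not allowed; first offending cells: ",
         paste(utils::head(sprintf("[%d,%d]", bad[, 1L], bad[, 2L]), 5L),
               collapse = ", "))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(variable_ids)) variable_ids <- paste0("V", seq_len(p))
  sample_ids <- as.character(sample_ids)
  variable_ids <- as.character(variable_ids)
  if (length(sample_ids) != n || anyDuplicated(sample_ids))
    stop("'sample_ids' must be ", n, " unique strings")
  if (length(variable_ids) != p || anyDuplicated(variable_ids))
    stop("'variable_ids' must be ", p, " unique strings")
  dimnames(values) <- list(sample_ids, variable_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 variable_ids = variable_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix: ", length(x$sample_ids), " samples x ",
      length(x$variable_ids), " variables\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values

#' Read an expression matrix from a delimited text file
#'
#' Reads a tab- or comma-delimited text file with a header row and row
#' labels into an [expression_matrix()]. The on-disk orientation is declared
#' by the caller and the result always has samples in rows.
#'
#' @param path path to a delimited text file. The delimiter is sniffed from
#'   the header line (tab preferred, then comma).
#' @param orientation `"samples_in_rows"` (default) if file rows are samples,
#'   `"variables_in_rows"` if file rows are genomic variables.
#'
#' @return An [expression_matrix()] with `n` samples by `p` variables.
#'
#' @details Missing (`NA`/empty) and non-numeric cells are errors; the error
#'   message names the offending row and column labels. Duplicate sample or
#'   variable identifiers are rejected.
#'
#' @seealso [write_enrichment_result()], [read_gene_sets_gmt()]
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples_in_rows",
                                                   "variables_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "NaN", ""),
                          colClasses = NA, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    num <- suppressWarnings(apply(df, 2L, function(col) as.numeric(col)))
    bad <- which(is.na(num) & !is.na(as.matrix(df)), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("non-numeric cells in ", path, ": ",
           paste(utils::head(sprintf("row '%s', column '%s'",
                                     rownames(df)[bad[, 1L]],
                                     colnames(df)[bad[, 2L]]), 5L),
                 collapse = "; "))
    m <- num
    dimnames(m) <- dimnames(df)
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing values in ", path, ": ",
         paste(utils::head(sprintf("row '%s', column '%s'",
                                   rownames(m)[bad[, 1L]],
                                   colnames(m)[bad[, 2L]]), 5L),
               collapse = "; "))
  }
  if (orientation == "variables_in_rows") m <- t(m)
  expression_matrix(m)
}
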