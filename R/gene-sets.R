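#' Construct a gene set collection
#'
#' A collection of `f` gene sets over a universe of `p` genomic variables,
#' stored as an `f x p` binary membership (annotation) matrix. Columns are
#' aligned to an expression matrix by variable identifier, never by position
#' alone.
#'
#' @param membership binary matrix (`f` sets by `p` variables) with entries
#'   in `{0, 1}`, or a named list of character vectors of member ids (a
#'   membership matrix is then built against `variable_ids`).
#' @param set_names character vector of `f` unique set names. Defaults to
#'   the row names of `membership` (or list names).
#' @param variable_ids character vector of `p` variable identifiers defining
#'   the universe, aligned to the expression matrix.
#'
#' @return An object of class `"gene_set_collection"`: a list with elements
#'   `membership` (integer 0/1 matrix), `set_names` and `variable_ids`.
#'
#' @details Every set must have at least one member; empty sets are an
#'   error here (drop them before construction, as [read_gene_sets_gmt()]
#'   does).
#'
#' @examples
#' gs <- gene_set_collection(list(a = c("g1", "g2"), b = "g3"),
#'                           variable_ids = paste0("g", 1:4))
#' gs$membership
#' @export
gene_set_collection <- function(membership, set_names = NULL, variable_ids) {
  variable_ids <- as.character(variable_ids)
  if (anyDuplicated(variable_ids))
    stop("'variable_ids' must be unique")
  if (is.list(membership)) {
    if (is.null(set_names)) set_names <- names(membership)
    mm <- matrix(0L, nrow = length(membership), ncol = length(variable_ids),
                 dimnames = list(set_names, variable_ids))
    for (i in seq_along(membership))
      mm[i, intersect(membership[[i]], variable_ids)] <- 1L
    membership <- mm
  } else {
    membership <- as.matrix(membership)
    storage.mode(membership) <- "integer"
    if (is.null(set_names)) set_names <- rownames(membership)
  }
  if (ncol(membership) != length(variable_ids))
    stop("membership matrix has ", ncol(membership),
         " columns but there are ", length(variable_ids), " variable ids")
  if (!all(membership %in% c(0L, 1L)))
    stop("membership entries must be 0 or 1")
  if (is.null(set_names)) set_names <- paste0("set", seq_len(nrow(membership)))
  set_names <- as.character(set_names)
  if (length(set_names) != nrow(membership) || anyDuplicated(set_names))
    stop("'set_names' must be ", nrow(membership), " unique strings")
  sizes <- rowSums(membership)
  if (any(sizes < 1L))
    stop("empty gene sets are not allowed: ",
         paste(set_names[sizes < 1L], collapse = ", "))
  dimnames(membership) <- list(set_names, variable_ids)
  structure(list(membership = membership, set_names = set_names,
                 variable_ids = variable_ids),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- rowSums(x$membership)
  cat("Gene set collection: ", nrow(x$membership), " sets over ",
      ncol(x$membership), " variables (sizes ", min(sizes), "-", max(sizes),
      ")\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) nrow(x$membership)

#' Read gene sets from a GMT file
#'
#' Parses a Broad/MSigDB-dialect GMT file (one set per line:
#' name, description, then member ids, tab-separated), intersects each set
#' with the supplied variable universe and applies size filters. Set sizes
#' are counted after the intersection, matching the convention used when
#' filtering MSigDB collections against a chip's measured genes.
#'
#' @param path path to a GMT file.
#' @param variable_ids character vector defining the variable universe
#'   (typically `x$variable_ids` of the expression matrix to be tested).
#' @param min_size,max_size post-intersection size filters. Defaults 15 and
#'   200, the customary values for curated MSigDB collections; simulated
#'   collections are built directly with [make_gene_sets()] and skip
#'   filtering.
#'
#' @return A [gene_set_collection()] containing only the sets whose
#'   post-intersection size lies in `[min_size, max_size]`.
#'
#' @details Members absent from `variable_ids` are silently dropped; the
#'   total number of dropped annotations is reported via [message()]. Sets
#'   with zero surviving members are dropped, not an error. An empty GMT
#'   file is an error.
#' @export
read_gene_sets_gmt <- function(path, variable_ids, min_size = 15L,
                               max_size = 200L) {
  if (!file.exists(path)) stop("file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L) stop("no gene sets found in ", path)
  variable_ids <- as.character(variable_ids)
  kept <- lapply(sets, intersect, y = variable_ids)
  dropped <- sum(lengths(sets)) - sum(lengths(kept))
  if (dropped > 0L)
    message(dropped, " gene set annotations were outside the variable ",
            "universe and dropped")
  sizes <- lengths(kept)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep))
    stop("no gene sets with post-intersection size in [", min_size, ", ",
         max_size, "]")
  gene_set_collection(kept[keep], variable_ids = variable_ids)
}

#' Align a gene set collection to an expression matrix
#'
#' Reorders (and checks) the columns of the membership matrix so they match
#' the variable order of an expression matrix. Alignment is by identifier.
#'
#' @param sets a [gene_set_collection()].
#' @param variable_ids target variable ordering.
#' @return A [gene_set_collection()] with columns in `variable_ids` order.
#' @keywords internal
align_gene_sets <- function(sets, variable_ids) {
  variable_ids <- as.character(variable_ids)
  idx <- match(variable_ids, sets$variable_ids)
  if (anyNA(idx))
    stop("gene set collection lacks ", sum(is.na(idx)),
         " of the expression matrix's variables (e.g. ",
         paste(utils::head(variable_ids[is.na(idx)], 3L), collapse = ", "),
         "); rebuild the collection against the expression universe")
  gene_set_collection(sets$membership[, idx, drop = FALSE],
                      set_names = sets$set_names,
                      variable_ids = variable_ids)
}
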