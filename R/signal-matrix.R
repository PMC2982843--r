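#' Genes-by-arrays signal matrix
#'
#' Container for nonnegative array signals: a numeric matrix with genes in
#' rows and arrays in columns, missing values as `NA`, and a grouping of
#' arrays into experiments (biological replicates share an experiment).
#'
#' @param values Numeric matrix, genes x arrays, nonnegative or `NA`.
#'   Row names are gene ids, column names array ids.
#' @param experiment Integer vector, one entry per array, assigning each
#'   array to an experiment.
#' @return An object of class `signal_matrix`.
#' @export
signal_matrix <- function(values, experiment) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique row names (gene ids)")
  if (is.null(colnames(values)))
    stop("`values` must have column names (array ids)")
  experiment <- as.integer(experiment)
  if (length(experiment) != ncol(values))
    stop("`experiment` must assign every array to exactly one experiment")
  if (any(values < 0, na.rm = TRUE))
    stop("signal values must be nonnegative")
  structure(
    list(values = values, experiment = experiment),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf(
    "signal_matrix: %d genes x %d arrays in %d experiments (%.1f%% missing)\n",
    nrow(x$values), ncol(x$values), length(unique(x$experiment)),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
array_ids <- function(x) colnames(x$values)

#' Subset a signal matrix by gene
#'
#' @param x A [signal_matrix()].
#' @param genes Character vector of gene ids to keep, in order.
#' @return A `signal_matrix` restricted to `genes`.
#' @export
subset_genes <- function(x, genes) {
  if (!all(genes %in% gene_ids(x))) stop("unknown gene ids in `genes`")
  signal_matrix(x$values[genes, , drop = FALSE], x$experiment)
}

check_genes_aligned <- function(a_ids, b_ids, what = "tables") {
  if (length(a_ids) != length(b_ids) || !all(a_ids == b_ids))
    stop(sprintf("%s are not aligned on gene_id", what))
  invisible(TRUE)
}
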