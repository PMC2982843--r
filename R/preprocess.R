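#' Normalize run-on signals to a genomic-DNA reference
#'
#' Divides each signal by the genomic-DNA hybridization of the same
#' filter, cancelling probe amount and length: the normalized value is
#' signal per unit of probe DNA. Missing signals propagate; a zero or
#' missing gDNA value where signal is present makes the value missing and
#' is counted in the attached QC report.
#'
#' @param signal A [signal_matrix()] of GRO (or other) signals.
#' @param gdna A [signal_matrix()] of genomic-DNA reference signals, either
#'   with the same arrays as `signal` or with a single array applied to all.
#' @return A `signal_matrix` of normalized values, with an attribute
#'   `n_invalid_gdna` counting values lost to unusable gDNA.
#' @export
normalize_to_gdna <- function(signal, gdna) {
  check_genes_aligned(gene_ids(signal), gene_ids(gdna), "signal and gdna")
  g <- gdna$values
  if (ncol(g) == 1 && ncol(signal$values) > 1) {
    g <- g[, rep(1L, ncol(signal$values)), drop = FALSE]
  } else if (ncol(g) != ncol(signal$values)) {
    stop("gdna must have one array or match the signal arrays")
  }
  bad <- (!is.na(signal$values)) & (is.na(g) | g <= 0)
  out <- signal$values / ifelse(is.na(g) | g <= 0, NA_real_, g)
  out[bad] <- NA_real_
  res <- signal_matrix(out, signal$experiment)
  attr(res, "n_invalid_gdna") <- sum(bad)
  res
}

#' Scale arrays to a common median
#'
#' Divides each array by its median over the genes measured in every
#' array, making arrays comparable before averaging. Idempotent.
#'
#' @param matrix A [signal_matrix()].
#' @return A `signal_matrix` in which every array has median 1 over the
#'   complete genes.
#' @export
scale_arrays <- function(matrix) {
  v <- matrix$values
  complete <- complete.cases(v)
  if (!any(complete))
    stop("no gene is measured in all arrays; cannot scale")
  med <- apply(v[complete, , drop = FALSE], 2, median)
  bad <- !is.finite(med) | med <= 0
  if (any(bad))
    stop("array(s) with no usable values: ",
         paste(colnames(v)[bad], collapse = ", "))
  signal_matrix(sweep(v, 2, med, "/"), matrix$experiment)
}

#' Filter genes by number of valid experiments
#'
#' A gene's valid-measure count is the number of experiments in which it
#' has at least one non-missing replicate value. Genes below `min_valid`
#' are dropped and reported.
#'
#' @param matrix A [signal_matrix()] with experiment grouping.
#' @param min_valid Minimum number of valid experiments (default 5).
#' @return List with elements `matrix` (filtered `signal_matrix`) and
#'   `qc` (a `qc_report`, see [qc_report()]).
#' @export
filter_genes <- function(matrix, min_valid = 5L) {
  n_exp <- length(unique(matrix$experiment))
  if (min_valid > n_exp)
    stop("`min_valid` exceeds the number of experiments (", n_exp, ")")
  n_valid <- Reduce(`+`, lapply(unique(matrix$experiment), function(e) {
    as.integer(rowSums(!is.na(matrix$values[, matrix$experiment == e,
                                            drop = FALSE])) > 0)
  }))
  keep <- n_valid >= min_valid
  qc <- qc_report(
    kept_gene_ids = gene_ids(matrix)[keep],
    dropped = data.frame(
      gene_id = gene_ids(matrix)[!keep],
      reason = rep("insufficient_valid", sum(!keep)),
      stringsAsFactors = FALSE
    ),
    kept_experiment_ids = unique(matrix$experiment)
  )
  list(matrix = subset_genes(matrix, gene_ids(matrix)[keep]), qc = qc)
}

#' Quality-control report
#'
#' Records which genes and experiments survive filtering, the reason each
#' gene was dropped, and the pairwise Pearson matrix between experiment
#' profiles when computed.
#'
#' @param kept_gene_ids Character vector of retained genes.
#' @param dropped Data frame with columns `gene_id`, `reason`.
#' @param kept_experiment_ids Experiments retained.
#' @param pearson Optional symmetric correlation matrix between experiment
#'   profiles.
#' @return An object of class `qc_report`.
#' @export
qc_report <- function(kept_gene_ids = character(),
                      dropped = data.frame(gene_id = character(),
                                           reason = character(),
                                           stringsAsFactors = FALSE),
                      kept_experiment_ids = integer(),
                      pearson = NULL) {
  if (length(intersect(kept_gene_ids, dropped$gene_id)) > 0)
    stop("a gene cannot be both kept and dropped")
  structure(
    list(kept_gene_ids = kept_gene_ids, dropped = dropped,
         kept_experiment_ids = kept_experiment_ids, pearson = pearson),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d genes kept, %d dropped; experiments kept: %s\n",
              length(x$kept_gene_ids), nrow(x$dropped),
              paste(x$kept_experiment_ids, collapse = ", ")))
  invisible(x)
}

# experiment-level profiles: per-gene mean of log2 replicate values
experiment_profiles <- function(matrix) {
  exps <- sort(unique(matrix$experiment))
  v <- matrix$values
  v[!is.na(v) & v <= 0] <- NA  # nonpositive treated as missing in log domain
  lv <- log2(v)
  prof <- vapply(exps, function(e) {
    rowMeans(lv[, matrix$experiment == e, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(v)))
  matrix(prof, nrow = nrow(v))
}

#' Correlation-based experiment quality control
#'
#' Computes experiment-level profiles (per-gene mean of log2 replicate
#' values), the pairwise Pearson correlation between profiles over genes
#' complete in both, and keeps an experiment iff its median pairwise
#' correlation with the others reaches `min_pearson`.
#'
#' @param matrix A [signal_matrix()] with at least 2 experiments.
#' @param min_pearson Minimum acceptable median pairwise Pearson
#'   correlation (default 0.7).
#' @return A [qc_report()] with the Pearson matrix and kept experiments.
#' @export
qc_experiments <- function(matrix, min_pearson = 0.7) {
  exps <- sort(unique(matrix$experiment))
  if (length(exps) < 2) stop("need at least 2 experiments")
  prof <- experiment_profiles(matrix)
  r <- cor(prof, use = "pairwise.complete.obs")
  diag(r) <- 1
  dimnames(r) <- list(exps, exps)
  med <- vapply(seq_along(exps),
                function(i) median(r[i, -i]), numeric(1))
  keep <- med >= min_pearson
  qc_report(
    kept_gene_ids = gene_ids(matrix),
    kept_experiment_ids = exps[keep],
    pearson = r
  )
}

#' Average replicates and experiments to one signal per gene
#'
#' Two-stage mean on the linear scale: replicate values are averaged
#' within each kept experiment, then experiment means are averaged across
#' experiments with at least one value. Genes absent from the matrix
#' (e.g. removed by [filter_genes()]) are absent from the result.
#'
#' @param matrix A [signal_matrix()], typically gDNA-normalized, scaled
#'   and gene-filtered.
#' @param qc A [qc_report()] listing the kept experiments (from
#'   [qc_experiments()]); `NULL` keeps all.
#' @return Named numeric vector of per-gene averaged signal (arbitrary
#'   units); `NA` for genes with no value in any kept experiment.
#' @export
average_experiments <- function(matrix, qc = NULL) {
  exps <- sort(unique(matrix$experiment))
  if (!is.null(qc)) exps <- intersect(exps, qc$kept_experiment_ids)
  if (length(exps) == 0) stop("no experiments kept")
  per_exp <- vapply(exps, function(e) {
    rowMeans(matrix$values[, matrix$experiment == e, drop = FALSE],
             na.rm = TRUE)
  }, numeric(nrow(matrix$values)))
  per_exp <- matrix(per_exp, nrow = nrow(matrix$values))
  per_exp[is.nan(per_exp)] <- NA
  out <- rowMeans(per_exp, na.rm = TRUE)
  out[is.nan(out)] <- NA
  setNames(out, gene_ids(matrix))
}
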