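#' MA-style comparison of nascent versus indirect rates
#'
#' Builds the lowess-corrected log-ratio of nascent over indirect
#' transcription rates: `m = log2(tr / ind_tr)` plotted against
#' `a = log2(tr + ind_tr)`, with the amplitude-related trend removed by
#' subtracting a lowess fit of m on a (`m_corrected`). Genes with a
#' nonpositive or missing value in either rate are dropped and counted.
#'
#' @param tr Named vector of nascent rates (molecules/min).
#' @param ind_tr Named vector of indirect rates (molecules/min), aligned
#'   by name.
#' @param span Lowess span (default 0.2).
#' @return Data frame with columns `gene_id`, `m`, `a`, `m_corrected` and
#'   attribute `n_dropped`.
#' @export
ma_lowess_ratio <- function(tr, ind_tr, span = 0.2) {
  if (is.null(names(tr)) || is.null(names(ind_tr)))
    stop("`tr` and `ind_tr` must be named by gene")
  common <- intersect(names(tr), names(ind_tr))
  x <- tr[common]
  y <- ind_tr[common]
  ok <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  n_dropped <- length(common) - sum(ok)
  if (n_dropped > 0)
    message("ma_lowess_ratio: dropped ", n_dropped,
            " genes with nonpositive or missing rates")
  if (sum(ok) < 10) stop("need at least 10 genes with positive rates")
  m <- log2(x[ok] / y[ok])
  a <- log2(x[ok] + y[ok])
  out <- data.frame(
    gene_id = common[ok],
    m = unname(m),
    a = unname(a),
    m_corrected = unname(m - fit_lowess(a, m, span)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Welch t-test of a gene group against the rest
#'
#' Tests whether a group of genes differs in mean from its complement,
#' e.g. in the corrected log-ratio of nascent over indirect rates.
#' Unequal variances are assumed (Welch); a pooled-variance Student test
#' is available via `var_equal = TRUE`.
#'
#' @param values Numeric vector (e.g. `m_corrected`).
#' @param group_mask Logical vector marking group membership; both the
#'   group and its complement need at least 2 values.
#' @param var_equal Pool variances (classical Student test) instead of
#'   Welch. Default `FALSE`.
#' @return List with `t_statistic`, `p_value` (two-sided), `group_mean`,
#'   `complement_mean`, `n_group`, `n_complement`.
#' @export
group_mean_test <- function(values, group_mask, var_equal = FALSE) {
  stopifnot(length(values) == length(group_mask), is.logical(group_mask))
  ok <- !is.na(values) & !is.na(group_mask)
  g <- values[ok & group_mask]
  c_ <- values[ok & !group_mask]
  if (length(g) < 2 || length(c_) < 2)
    stop("both the group and its complement need at least 2 values")
  ht <- t.test(g, c_, var.equal = var_equal)
  list(
    t_statistic = unname(ht$statistic),
    p_value = ht$p.value,
    group_mean = mean(g),
    complement_mean = mean(c_),
    n_group = length(g),
    n_complement = length(c_)
  )
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, computed on pairwise
#' complete observations.
#'
#' @param x,y Aligned numeric vectors with at least 3 complete pairs.
#' @return Spearman rho.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  cor(x[ok], y[ok], method = "spearman")
}

#' Share of total transcription held by the most transcribed genes
#'
#' Percentage of the summed transcription rate contributed by the top
#' fraction of genes (`ceiling(top_fraction * n)` largest values).
#'
#' @param tr Nonnegative transcription rates, total > 0.
#' @param top_fraction Fraction of genes in (0, 1].
#' @return Percentage of the grand total.
#' @export
transcription_share <- function(tr, top_fraction) {
  tr <- tr[!is.na(tr)]
  if (length(tr) == 0) stop("empty input")
  stopifnot(top_fraction > 0, top_fraction <= 1, all(tr >= 0))
  total <- sum(tr)
  if (total <= 0) stop("total transcription must be positive")
  k <- ceiling(top_fraction * length(tr))
  100 * sum(sort(tr, decreasing = TRUE)[seq_len(k)]) / total
}

#' Distribution summary of transcription rates
#'
#' Median, 5th and 95th percentiles (linear interpolation between order
#' statistics, R quantile type 7) and mean.
#'
#' @param tr Numeric vector (NA dropped).
#' @return Named list `median`, `p5`, `p95`, `mean`.
#' @export
summary_stats <- function(tr) {
  tr <- tr[!is.na(tr)]
  if (length(tr) < 1) stop("need at least one value")
  q <- quantile(tr, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  list(median = q[2], p5 = q[1], p95 = q[3], mean = mean(tr))
}
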