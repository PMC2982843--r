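#' Standardize positive signals on the log2 scale
#'
#' Changes the values to log2 scale, subtracts the population mean and
#' divides by the standard deviation (sample sd, n - 1 denominator), so
#' that `mean(z) == 0` and `sd(z) == 1`. The parameters are returned so
#' the standardization can be reversed after correction.
#'
#' @param values Strictly positive numeric vector (nonpositive values must
#'   be filtered upstream). Names are carried through.
#' @return List with elements `z` (standardized log2 values) and `params`
#'   (list `mean_log2`, `sd_log2`).
#' @seealso [invert_zscore()]
#' @export
log2_zscore <- function(values) {
  bad <- !is.finite(values) | values <= 0
  if (any(bad)) {
    ids <- if (!is.null(names(values))) names(values)[bad] else which(bad)
    stop("nonpositive or non-finite values for: ",
         paste(head(ids, 10), collapse = ", "))
  }
  lv <- log2(values)
  m <- mean(lv)
  s <- sd(lv)
  if (!is.finite(s) || s == 0) stop("constant input: sd of log2 values is 0")
  list(z = (lv - m) / s, params = list(mean_log2 = m, sd_log2 = s))
}

#' Reverse a log2 z-score standardization
#'
#' Multiplies each value by the original standard deviation and adds back
#' the population mean; with `delog = TRUE` also undoes the log2
#' transform, returning strictly positive arbitrary units.
#'
#' @param z Standardized values.
#' @param params `params` element returned by [log2_zscore()].
#' @param delog If `TRUE` (default) return `2^(z * sd + mean)`; otherwise
#'   stay on the log2 scale.
#' @return Numeric vector on the log2 or linear scale.
#' @export
invert_zscore <- function(z, params, delog = TRUE) {
  out <- z * params$sd_log2 + params$mean_log2
  if (delog) 2^out else out
}

#' Locally weighted scatterplot smoothing (lowess)
#'
#' Local linear regression with tricube weights and nearest-neighbour
#' bandwidth `span`, no robustness iterations, evaluated at every observed
#' x (Cleveland's lowess with `iter = 0`, `delta = 0`). Fitted values are
#' returned in the input order; ties in x are resolved by stable input
#' order.
#'
#' @param x,y Numeric vectors of equal length (>= 5), no missing values.
#' @param span Fraction of the data in each local neighbourhood,
#'   in (0, 1] (default 0.2).
#' @return Numeric vector of fitted values aligned to `x`.
#' @export
fit_lowess <- function(x, y, span = 0.2) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 5) stop("need at least 5 points for lowess")
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1]")
  if (span * n < 2) stop("`span` * n must be at least 2")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed in lowess")
  o <- order(x)
  fit <- lowess(x[o], y[o], f = span, iter = 0, delta = 0)$y
  out <- numeric(n)
  out[o] <- fit
  out
}

#' Remove the probe-length bias by dual lowess against a pol II reference
#'
#' The run-on signal carries a probe-length artifact (3'-ward accumulation
#' of run-on label, with a regime change at the 3 kb probe-design
#' boundary) that the pol II ChIP signal largely lacks. Both signals are
#' supplied as log2 z-scores; within each length regime (below / at or
#' above `split_bp`) a lowess of each signal on ORF length is fitted, and
#' the difference between the two smoothers is subtracted from the run-on
#' z-scores:
#' `corrected_i = gro_z_i - (fit_gro(length_i) - fit_rpcc(length_i))`.
#' Genes of exactly `split_bp` fall in the upper regime.
#'
#' @param gro_z,rpcc_z Standardized log2 signals (from [log2_zscore()]),
#'   aligned to `lengths_bp`.
#' @param lengths_bp Integer ORF lengths in bp.
#' @param split_bp Regime boundary in bp (default 3000, the probe-design
#'   change point).
#' @param span Lowess span (default 0.2).
#' @return Corrected `gro_z` vector.
#' @export
dual_lowess_correct <- function(gro_z, rpcc_z, lengths_bp,
                                split_bp = 3000L, span = 0.2) {
  n <- length(gro_z)
  if (length(rpcc_z) != n || length(lengths_bp) != n)
    stop("`gro_z`, `rpcc_z` and `lengths_bp` must be aligned")
  upper <- lengths_bp >= split_bp
  min_n <- max(5, ceiling(2 / span))
  for (regime in list(!upper, upper)) {
    if (sum(regime) < min_n)
      stop("a length regime has fewer than ", min_n, " genes; ",
           "consider a single-regime fit (split_bp = Inf)")
  }
  corrected <- numeric(n)
  for (regime in list(!upper, upper)) {
    x <- lengths_bp[regime]
    bias <- fit_lowess(x, gro_z[regime], span) -
      fit_lowess(x, rpcc_z[regime], span)
    corrected[regime] <- gro_z[regime] - bias
  }
  names(corrected) <- names(gro_z)
  corrected
}

#' One-call probe-length bias correction on linear-scale signals
#'
#' Convenience wrapper: standardizes GRO and RPCC signals with
#' [log2_zscore()], applies [dual_lowess_correct()], and reverses the GRO
#' standardization (optionally back to linear arbitrary units).
#'
#' @param gro_au,rpcc_au Strictly positive per-gene signals (arbitrary
#'   units), aligned to `lengths_bp`.
#' @param lengths_bp ORF lengths in bp.
#' @param split_bp,span See [dual_lowess_correct()].
#' @param delog Return linear arbitrary units (default) or log2.
#' @return Corrected GRO signal vector, same units as the input when
#'   `delog = TRUE`.
#' @export
correct_length_bias <- function(gro_au, rpcc_au, lengths_bp,
                                split_bp = 3000L, span = 0.2, delog = TRUE) {
  gro <- log2_zscore(gro_au)
  rpcc <- log2_zscore(rpcc_au)
  z <- dual_lowess_correct(gro$z, rpcc$z, lengths_bp, split_bp, span)
  invert_zscore(z, gro$params, delog = delog)
}
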