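# Independent oracles and fixture builders used across the suite.

# Brute-force lowess oracle: local linear regression with tricube weights
# over the ceil-span nearest neighbours, as in Cleveland's definition.
# Written directly from the definition, independent of stats::lowess.
lowess_oracle <- function(x, y, span) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  ys <- y[o]
  ns <- max(2L, min(n, as.integer(span * n + 1e-7)))
  rng <- max(xs) - min(xs)
  fit <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(xs - xs[i])
    idx <- order(d)[seq_len(ns)]
    h <- max(d[idx])
    w <- numeric(n)
    if (h > 0) {
      w <- ifelse(d <= 0.001 * h, 1,
                  ifelse(d <= 0.999 * h, (1 - (d / h)^3)^3, 0))
    } else {
      w[d == 0] <- 1
    }
    w[-idx] <- 0
    sw <- sum(w)
    wx <- sum(w * xs) / sw
    ss <- sum(w * (xs - wx)^2)
    fit[i] <- if (ss > 0 && sqrt(ss) > 1e-3 * rng) {
      sum(w * ys) / sw + sum(w * (xs - wx) * ys) / ss * (xs[i] - wx)
    } else {
      sum(w * ys) / sw
    }
  }
  out <- numeric(n)
  out[o] <- fit
  out
}

# Numeric quadrature of the run-on labeling integral d * int_a^b min(delta, y) dy
gro_quadrature_oracle <- function(density_per_nt, a, b, delta) {
  density_per_nt * stats::integrate(function(y) pmin(delta, y), a, b,
                                    rel.tol = 1e-10)$value
}

# Noise-free simulation configuration (deterministic expected signals)
quiet_config <- function(...) {
  simulation_config(noise_cv = 0, array_scale_sd = 0, missing_rate = 0, ...)
}

# Small aligned catalog + truth with hand-set kinetics
toy_truth <- function(lengths, density_per_kb,
                      constants = kinetic_constants()) {
  catalog <- catalog_from_lengths(lengths)
  tr <- density_per_kb * elongation_kb_per_min(constants)
  hl <- rep(20, length(lengths))
  kd <- log(2) / hl
  truth <- data.frame(
    gene_id = catalog$gene_id,
    true_tr = tr,
    half_life_min = hl,
    kd = kd,
    ra_true = tr / (kd + dilution_rate(constants)),
    true_density = density_per_kb,
    stringsAsFactors = FALSE
  )
  list(catalog = catalog, truth = truth)
}

# Build a signal_matrix from a plain matrix with default naming
sm <- function(values, experiment = rep(1L, ncol(values)),
               gene_id = sprintf("g%05d", seq_len(nrow(values)))) {
  rownames(values) <- gene_id
  if (is.null(colnames(values)))
    colnames(values) <- paste0("exp", experiment, "_rep",
                               stats::ave(experiment, experiment,
                                          FUN = seq_along))
  signal_matrix(values, experiment)
}
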