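#' Configuration of the synthetic transcription dataset
#'
#' Parameters of the simulated genome and array experiment. The defaults
#' describe an exponentially growing yeast population measured on nylon
#' macroarrays: log-normal true transcription rates centred on the
#' observed genome-wide median (0.12 molecules/min) with a 90% range
#' matching 2.33-29.7 mRNAs/hour, log-normal mRNA half-lives around 20
#' minutes, a run-on labeling extension of 300 nt producing the 3'-ward
#' length bias, a mild negative length trend in the pol II ChIP signal,
#' 20% multiplicative noise and 5% missing values.
#'
#' @param n_genes Number of genes to simulate.
#' @param seed Integer seed; every stochastic stage derives its stream from
#'   it, so equal seeds give byte-identical outputs.
#' @param tr_log10_mean,tr_log10_sd Mean and sd of log10 true transcription
#'   rate (molecules/min).
#' @param halflife_log10_mean,halflife_log10_sd Mean and sd of log10 mRNA
#'   half-life (min).
#' @param length_log10_mean,length_log10_sd Mean and sd of log10 ORF
#'   length (bp).
#' @param runon_extension_nt Run-on labeling extension: each elongating
#'   polymerase incorporates label over at most this many nt downstream of
#'   its position (nt).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise applied per value.
#' @param array_scale_sd sdlog of the log-normal array-level scale factor
#'   (global intensity differences between hybridizations).
#' @param missing_rate Probability that any single measurement is missing.
#' @param rpcc_length_bias_exponent Exponent of the pol II ChIP length
#'   trend: expected signal scales with `(length_kb)^exponent`.
#' @param n_experiments,reps_per_experiment Run-on experiment layout
#'   (default 8 experiments in triplicate, 24 arrays).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 5000L,
                              seed = 1L,
                              tr_log10_mean = -0.92,
                              tr_log10_sd = 0.34,
                              halflife_log10_mean = 1.3,
                              halflife_log10_sd = 0.25,
                              length_log10_mean = 3.15,
                              length_log10_sd = 0.25,
                              runon_extension_nt = 300L,
                              noise_cv = 0.2,
                              array_scale_sd = 0.2,
                              missing_rate = 0.05,
                              rpcc_length_bias_exponent = -0.05,
                              n_experiments = 8L,
                              reps_per_experiment = 3L) {
  stopifnot(
    n_genes >= 0,
    runon_extension_nt > 0,
    noise_cv >= 0, array_scale_sd >= 0,
    missing_rate >= 0, missing_rate < 1,
    tr_log10_sd > 0, halflife_log10_sd > 0, length_log10_sd > 0,
    n_experiments >= 1, reps_per_experiment >= 1
  )
  structure(
    list(
      n_genes = as.integer(n_genes), seed = as.integer(seed),
      tr_log10_mean = tr_log10_mean, tr_log10_sd = tr_log10_sd,
      halflife_log10_mean = halflife_log10_mean,
      halflife_log10_sd = halflife_log10_sd,
      length_log10_mean = length_log10_mean,
      length_log10_sd = length_log10_sd,
      runon_extension_nt = as.integer(runon_extension_nt),
      noise_cv = noise_cv, array_scale_sd = array_scale_sd,
      missing_rate = missing_rate,
      rpcc_length_bias_exponent = rpcc_length_bias_exponent,
      n_experiments = as.integer(n_experiments),
      reps_per_experiment = as.integer(reps_per_experiment)
    ),
    class = "simulation_config"
  )
}

# log-normal deviates with unit mean and a given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# per-stage seed streams derived from the master seed
stage_seed <- function(seed, offset) (as.integer(seed) %% 1000000L) * 1000L + offset

#' Generate a synthetic gene catalog with the macroarray probe design
#'
#' ORF lengths are drawn log-normally (rounded to bp, floored at 150 bp).
#' Probes follow the array design rule: the complete ORF for genes shorter
#' than 3 kb, the 3'-terminal 1 kb for longer genes. Probe coordinates are
#' 0-based half-open, relative to the ORF start.
#'
#' @param n_genes Number of genes (>= 0).
#' @param seed Integer seed.
#' @param length_log10_mean,length_log10_sd log10 ORF length distribution.
#' @return A data frame with columns `gene_id`, `orf_length_bp`,
#'   `probe_start_bp`, `probe_end_bp`.
#' @examples
#' cat3 <- generate_gene_catalog(3, seed = 1)
#' @export
generate_gene_catalog <- function(n_genes, seed = 1L,
                                  length_log10_mean = 3.15,
                                  length_log10_sd = 0.25) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 0)
    stop("`n_genes` must be a nonnegative integer")
  stopifnot(is.finite(length_log10_mean), is.finite(length_log10_sd),
            length_log10_sd > 0)
  n_genes <- as.integer(n_genes)
  if (n_genes == 0) {
    return(data.frame(gene_id = character(), orf_length_bp = integer(),
                      probe_start_bp = integer(), probe_end_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  lengths <- withr::with_seed(stage_seed(seed, 1L), {
    pmax(150L, as.integer(round(10^rnorm(n_genes, length_log10_mean,
                                         length_log10_sd))))
  })
  catalog_from_lengths(lengths)
}

#' Build a gene catalog from explicit ORF lengths
#'
#' Applies the probe design rule deterministically to user-supplied
#' lengths; useful for constructing small test genomes.
#'
#' @param orf_length_bp Integer vector of ORF lengths (bp, >= 1).
#' @param gene_id Optional gene ids; default `g0001`, `g0002`, ...
#' @return A gene catalog data frame (see [generate_gene_catalog()]).
#' @export
catalog_from_lengths <- function(orf_length_bp, gene_id = NULL) {
  stopifnot(all(orf_length_bp >= 1))
  n <- length(orf_length_bp)
  if (is.null(gene_id))
    gene_id <- sprintf("g%05d", seq_len(n))
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  orf_length_bp <- as.integer(orf_length_bp)
  probe_start <- ifelse(orf_length_bp < 3000L, 0L, orf_length_bp - 1000L)
  data.frame(
    gene_id = as.character(gene_id),
    orf_length_bp = orf_length_bp,
    probe_start_bp = as.integer(probe_start),
    probe_end_bp = orf_length_bp,
    stringsAsFactors = FALSE
  )
}

#' Generate ground-truth transcription kinetics
#'
#' Draws true transcription rates and mRNA half-lives log-normally, then
#' derives the degradation rate `kd = ln2 / half_life`, the steady-state
#' abundance `ra = tr / (kd + ln2 / doubling_time)` (synthesis balances
#' degradation plus growth dilution), and the elongating polymerase
#' density `tr / speed` in molecules/kb (the flux of polymerases past any
#' point of the gene equals the transcription rate).
#'
#' @param catalog Gene catalog from [generate_gene_catalog()].
#' @param constants A [kinetic_constants()] object.
#' @param config A [simulation_config()].
#' @return A data frame with columns `gene_id`, `true_tr` (molecules/min),
#'   `half_life_min`, `kd` (1/min), `ra_true` (molecules/cell),
#'   `true_density` (molecules/kb).
#' @export
generate_true_kinetics <- function(catalog, constants = kinetic_constants(),
                                   config = simulation_config()) {
  if (nrow(catalog) == 0) stop("catalog is empty")
  stopifnot(config$tr_log10_sd > 0, config$halflife_log10_sd > 0)
  n <- nrow(catalog)
  draws <- withr::with_seed(stage_seed(config$seed, 2L), {
    list(tr = 10^rnorm(n, config$tr_log10_mean, config$tr_log10_sd),
         hl = 10^rnorm(n, config$halflife_log10_mean, config$halflife_log10_sd))
  })
  kd <- log(2) / draws$hl
  data.frame(
    gene_id = catalog$gene_id,
    true_tr = draws$tr,
    half_life_min = draws$hl,
    kd = kd,
    ra_true = draws$tr / (kd + dilution_rate(constants)),
    true_density = draws$tr / elongation_kb_per_min(constants),
    stringsAsFactors = FALSE
  )
}

#' Expected run-on signal over a probe (closed form)
#'
#' Under the labeling model, elongating polymerases sit uniformly at
#' density `d` per nt and each incorporates label over the next
#' `min(delta, L - x)` nt. The expected number of labeled nucleotides at
#' distance `y` from the ORF start is then `d * min(delta, y)`, and the
#' probe signal is its integral over the probe interval `[a, b)`:
#' \deqn{d \int_a^b \min(\delta, y)\,dy}
#' evaluated in closed form. This reproduces the 3'-ward labeling bias and
#' its regime change at the 3 kb probe-design boundary.
#'
#' @param density_per_nt Polymerase density per nt (vector).
#' @param probe_start_bp,probe_end_bp Probe interval, 0-based half-open,
#'   relative to ORF start (vectors).
#' @param extension_nt Labeling extension delta in nt (> 0, scalar).
#' @return Expected labeled-nt count per gene.
#' @export
gro_expected_signal <- function(density_per_nt, probe_start_bp, probe_end_bp,
                                extension_nt) {
  if (length(extension_nt) != 1 || extension_nt <= 0)
    stop("`extension_nt` must be a single positive number")
  a <- probe_start_bp
  b <- probe_end_bp
  d <- extension_nt
  integral <- ifelse(
    b <= d, (b^2 - a^2) / 2,
    ifelse(a >= d, d * (b - a), (d^2 - a^2) / 2 + d * (b - d))
  )
  density_per_nt * integral
}

simulate_arrays <- function(expected, gene_id, n_arrays, experiment, config,
                            seed_offset, missing = TRUE, prefix = "exp") {
  n <- length(expected)
  values <- withr::with_seed(stage_seed(config$seed, seed_offset), {
    scale <- if (config$array_scale_sd == 0) rep(1, n_arrays) else
      rlnorm(n_arrays, -config$array_scale_sd^2 / 2, config$array_scale_sd)
    noise <- matrix(rlnorm_cv(n * n_arrays, config$noise_cv), n, n_arrays)
    v <- outer(expected, scale) * noise
    if (missing && config$missing_rate > 0) {
      v[matrix(runif(n * n_arrays) < config$missing_rate, n, n_arrays)] <- NA
    }
    v
  })
  rownames(values) <- gene_id
  colnames(values) <- paste0(prefix, experiment, "_rep",
                             unlist(lapply(table(experiment), seq_len)))
  signal_matrix(values, experiment)
}

#' Simulate genomic run-on (GRO) arrays
#'
#' Expected signals follow the closed-form labeling model of
#' [gro_expected_signal()]; each array receives an independent log-normal
#' scale factor, per-value log-normal noise at `noise_cv`, and missing
#' values at `missing_rate`. The layout is `n_experiments` experiments in
#' `reps_per_experiment` replicates.
#'
#' @param truth Truth table from [generate_true_kinetics()].
#' @param catalog Matching gene catalog.
#' @param config A [simulation_config()].
#' @return A [signal_matrix()] of GRO signals.
#' @export
simulate_gro_arrays <- function(truth, catalog, config = simulation_config()) {
  check_genes_aligned(truth$gene_id, catalog$gene_id, "truth and catalog")
  expected <- gro_expected_signal(
    truth$true_density / 1000,
    catalog$probe_start_bp, catalog$probe_end_bp,
    config$runon_extension_nt
  )
  n_arrays <- config$n_experiments * config$reps_per_experiment
  experiment <- rep(seq_len(config$n_experiments),
                    each = config$reps_per_experiment)
  simulate_arrays(expected, truth$gene_id, n_arrays, experiment, config,
                  seed_offset = 3L)
}

#' Simulate RNA pol II ChIP-on-chip (RPCC) arrays
#'
#' Expected signal is proportional to the true polymerase density with a
#' mild power-law length trend `(length_kb)^rpcc_length_bias_exponent`,
#' measured on one experiment in triplicate with log-normal noise.
#'
#' @inheritParams simulate_gro_arrays
#' @return A [signal_matrix()] of RPCC signals.
#' @export
simulate_rpcc_arrays <- function(truth, catalog, config = simulation_config()) {
  check_genes_aligned(truth$gene_id, catalog$gene_id, "truth and catalog")
  expected <- truth$true_density *
    (catalog$orf_length_bp / 1000)^config$rpcc_length_bias_exponent
  reps <- config$reps_per_experiment
  simulate_arrays(expected, truth$gene_id, reps, rep(1L, reps), config,
                  seed_offset = 4L, prefix = "rpcc")
}

#' Simulate genomic-DNA reference hybridizations
#'
#' Genomic DNA is present at one copy per gene, so the expected signal is
#' proportional to the probe length in bp (unit scale). One reference
#' array is simulated per GRO array; values are strictly positive and
#' never missing.
#'
#' @param catalog Gene catalog.
#' @param config A [simulation_config()].
#' @return A [signal_matrix()] matching the GRO array layout.
#' @export
simulate_gdna_reference <- function(catalog, config = simulation_config()) {
  if (nrow(catalog) == 0) stop("catalog is empty")
  expected <- as.numeric(catalog$probe_end_bp - catalog$probe_start_bp)
  n_arrays <- config$n_experiments * config$reps_per_experiment
  experiment <- rep(seq_len(config$n_experiments),
                    each = config$reps_per_experiment)
  simulate_arrays(expected, catalog$gene_id, n_arrays, experiment, config,
                  seed_offset = 5L, missing = FALSE, prefix = "gdna")
}

#' Simulate a reference absolute-abundance table
#'
#' Emulates a competitive-PCR style reference: the `n_ref` genes with the
#' highest true steady-state abundance, measured with multiplicative
#' log-normal noise, in molecules/cell.
#'
#' @param truth Truth table.
#' @param n_ref Number of reference genes (<= number of genes).
#' @param noise_cv Coefficient of variation of the measurement noise.
#' @param seed Integer seed.
#' @return Data frame with columns `gene_id`, `abundance` (molecules/cell),
#'   ordered by decreasing true abundance.
#' @export
simulate_reference_abundances <- function(truth, n_ref = 2000L,
                                          noise_cv = 0.2, seed = 1L) {
  if (n_ref > nrow(truth))
    stop("`n_ref` exceeds the number of genes in `truth`")
  ord <- order(-truth$ra_true, truth$gene_id)
  top <- head(ord, n_ref)
  noise <- withr::with_seed(stage_seed(seed, 6L),
                            rlnorm_cv(length(top), noise_cv))
  data.frame(
    gene_id = truth$gene_id[top],
    abundance = truth$ra_true[top] * noise,
    stringsAsFactors = FALSE
  )
}

#' Simulate relative mRNA abundances
#'
#' An RNA-Seq-like relative abundance table: proportional to the true
#' steady-state abundance in arbitrary units (unknown global scale) with
#' multiplicative log-normal noise.
#'
#' @param truth Truth table.
#' @param noise_cv Coefficient of variation of the measurement noise.
#' @param seed Integer seed.
#' @param scale Arbitrary global scale factor of the relative units.
#' @return Data frame with columns `gene_id`, `relative_ra`.
#' @export
simulate_relative_abundances <- function(truth, noise_cv = 0.2, seed = 1L,
                                         scale = 1e-3) {
  noise <- withr::with_seed(stage_seed(seed, 7L),
                            rlnorm_cv(nrow(truth), noise_cv))
  data.frame(
    gene_id = truth$gene_id,
    relative_ra = truth$ra_true * scale * noise,
    stringsAsFactors = FALSE
  )
}

#' Simulate a measured mRNA half-life table
#'
#' True half-lives observed with multiplicative log-normal noise, in
#' minutes, emulating a genomic mRNA stability dataset.
#'
#' @inheritParams simulate_relative_abundances
#' @return Data frame with columns `gene_id`, `half_life_min`.
#' @export
simulate_measured_half_lives <- function(truth, noise_cv = 0.2, seed = 1L) {
  noise <- withr::with_seed(stage_seed(seed, 8L),
                            rlnorm_cv(nrow(truth), noise_cv))
  data.frame(
    gene_id = truth$gene_id,
    half_life_min = truth$half_life_min * noise,
    stringsAsFactors = FALSE
  )
}
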