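#' Run the full synthetic-to-snapshot pipeline
#'
#' Executes every stage on a simulated dataset: genome and truth
#' generation, GRO/RPCC/gDNA array simulation, gDNA normalization, median
#' scaling, validity and correlation filters, two-stage averaging,
#' probe-length bias correction, abundance and nascent-rate calibration,
#' the per-gene rate table, the MA-style nascent/indirect comparison and
#' the genome-wide snapshot. With `out_dir` set, every stage's output is
#' written as TSV together with a JSON run manifest recording the
#' configuration and seed.
#'
#' @param config A [simulation_config()]; `config$seed` drives every
#'   source of randomness.
#' @param constants A [kinetic_constants()] object.
#' @param min_valid,min_pearson Preprocessing filters (see
#'   [filter_genes()], [qc_experiments()]).
#' @param split_bp,span Bias-correction parameters (see
#'   [dual_lowess_correct()]).
#' @param top_k Calibration anchor count (see [calibrate_abundance()],
#'   [calibrate_nascent()]).
#' @param compare Also compute the MA comparison table (default `TRUE`).
#' @param out_dir Optional output directory for TSV files and manifest.
#' @return List with elements `catalog`, `truth`, `qc_genes`,
#'   `qc_experiments`, `rates` (the [rate_table()]), `ma`, `snapshot`,
#'   `scale_factors`, `config`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         constants = kinetic_constants(),
                         min_valid = 5L, min_pearson = 0.7,
                         split_bp = 3000L, span = 0.2,
                         top_k = 2000L, compare = TRUE, out_dir = NULL) {
  # --- simulate -------------------------------------------------------
  catalog <- generate_gene_catalog(config$n_genes, config$seed,
                                   config$length_log10_mean,
                                   config$length_log10_sd)
  truth <- generate_true_kinetics(catalog, constants, config)
  gro <- simulate_gro_arrays(truth, catalog, config)
  rpcc <- simulate_rpcc_arrays(truth, catalog, config)
  gdna <- simulate_gdna_reference(catalog, config)
  reference <- simulate_reference_abundances(truth, n_ref = top_k,
                                             noise_cv = config$noise_cv,
                                             seed = config$seed)
  relative <- simulate_relative_abundances(truth, noise_cv = config$noise_cv,
                                           seed = config$seed)
  half_lives <- simulate_measured_half_lives(truth,
                                             noise_cv = config$noise_cv,
                                             seed = config$seed)

  # --- preprocess -----------------------------------------------------
  gro_norm <- scale_arrays(normalize_to_gdna(gro, gdna))
  filtered <- filter_genes(gro_norm, min_valid)
  qc_exp <- qc_experiments(filtered$matrix, min_pearson)
  gro_avg <- average_experiments(filtered$matrix, qc_exp)
  rpcc_avg <- average_experiments(scale_arrays(rpcc))

  # --- length-bias correction ----------------------------------------
  genes <- catalog$gene_id[
    catalog$gene_id %in% names(gro_avg) &
      is.finite(gro_avg[catalog$gene_id]) &
      is.finite(rpcc_avg[catalog$gene_id])
  ]
  genes <- genes[gro_avg[genes] > 0 & rpcc_avg[genes] > 0]
  lengths <- catalog$orf_length_bp[match(genes, catalog$gene_id)]
  tr_au <- correct_length_bias(gro_avg[genes], rpcc_avg[genes], lengths,
                               split_bp = split_bp, span = span)

  # --- kinetic calibration -------------------------------------------
  rel_vec <- setNames(relative$relative_ra, relative$gene_id)
  ra <- calibrate_abundance(rel_vec, reference, top_k)
  hl <- setNames(half_lives$half_life_min, half_lives$gene_id)
  ind <- indirect_tr(ra, hl[names(ra)], constants, include_dilution = TRUE)
  tr <- calibrate_nascent(tr_au, ind, top_k)
  rates <- rate_table(catalog, tr, tr_au, ra, hl, constants)

  # --- comparison and snapshot ---------------------------------------
  ma <- if (compare) ma_lowess_ratio(tr, ind, span) else NULL
  snapshot <- genome_totals(rates, constants)

  result <- list(
    catalog = catalog, truth = truth,
    qc_genes = filtered$qc, qc_experiments = qc_exp,
    rates = rates, ma = ma, snapshot = snapshot,
    scale_factors = c(abundance = attr(ra, "scale_factor"),
                      nascent = attr(tr, "scale_factor")),
    config = config
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(catalog, file.path(out_dir, "gene_catalog.tsv"))
    write_table(truth, file.path(out_dir, "truth.tsv"))
    write_signal_matrix(gro, file.path(out_dir, "gro_signals.tsv"))
    write_signal_matrix(rpcc, file.path(out_dir, "rpcc_signals.tsv"))
    write_signal_matrix(gdna, file.path(out_dir, "gdna_signals.tsv"))
    write_table(rates, file.path(out_dir, "rate_table.tsv"))
    if (!is.null(ma)) write_table(ma, file.path(out_dir, "ma_table.tsv"))
    write_table(
      data.frame(quantity = names(unlist(unclass(snapshot))),
                 value = unname(unlist(unclass(snapshot))),
                 stringsAsFactors = FALSE),
      file.path(out_dir, "snapshot.tsv")
    )
    dropped <- filtered$qc$dropped
    write_table(
      data.frame(gene_id = c(filtered$qc$kept_gene_ids, dropped$gene_id),
                 status = c(rep("kept", length(filtered$qc$kept_gene_ids)),
                            rep("dropped", nrow(dropped))),
                 reason = c(rep(NA_character_,
                                length(filtered$qc$kept_gene_ids)),
                            dropped$reason),
                 stringsAsFactors = FALSE),
      file.path(out_dir, "qc_genes.tsv")
    )
    manifest <- list(
      package = "nascentrates",
      version = as.character(utils::packageVersion("nascentrates")),
      seed = config$seed,
      config = unclass(config),
      constants = unclass(constants),
      parameters = list(min_valid = min_valid, min_pearson = min_pearson,
                        split_bp = split_bp, span = span, top_k = top_k)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  result
}
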