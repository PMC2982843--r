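#' Genome-wide transcriptional totals and turnover
#'
#' Sums the per-gene nascent rates and extrapolates to the whole genome
#' with the single factor `genome_gene_count / n_measured` (the measured
#' genes are assumed representative of all non-dubious ORFs). Derives
#' productive transcription events per minute and per cell cycle, the
#' turnover of the mRNA pool per cycle, and the total number of
#' elongating polymerase molecules.
#'
#' @param rates A [rate_table()] data frame (columns `tr`,
#'   `pols_per_gene`; `NA` rates are excluded from sums and counts).
#' @param constants A [kinetic_constants()] object.
#' @param extrapolate Apply the genome extrapolation factor (default
#'   `TRUE`); `FALSE` reports totals over the measured genes only.
#' @return Object of class `snapshot_summary`: list with
#'   `total_tr_per_hour` (mRNAs/h), `events_per_min`, `events_per_cycle`,
#'   `turnover_per_cycle`, `elongating_pols`, `n_measured`,
#'   `extrapolation_factor`.
#' @export
genome_totals <- function(rates, constants = kinetic_constants(),
                          extrapolate = TRUE) {
  if (is.null(rates) || nrow(rates) == 0) stop("empty rate table")
  ok <- !is.na(rates$tr)
  n <- sum(ok)
  if (n == 0) stop("no measured rates in table")
  factor <- if (extrapolate) constants$genome_gene_count / n else 1
  total_per_hour <- sum(rates$tr[ok]) * 60 * factor
  events_per_min <- total_per_hour / 60
  events_per_cycle <- events_per_min * constants$doubling_time_min
  structure(
    list(
      total_tr_per_hour = total_per_hour,
      events_per_min = events_per_min,
      events_per_cycle = events_per_cycle,
      turnover_per_cycle = events_per_cycle / constants$total_mrna_per_cell,
      elongating_pols = sum(rates$pols_per_gene[ok]) * factor,
      n_measured = n,
      extrapolation_factor = factor
    ),
    class = "snapshot_summary"
  )
}

#' @export
print.snapshot_summary <- function(x, ...) {
  cat(sprintf(
    paste0("snapshot_summary (%d genes measured, extrapolation x%.3f)\n",
           "  total transcription: %.0f mRNAs/h (%.0f events/min)\n",
           "  events per cell cycle: %.0f; mRNA pool turnover: %.2f\n",
           "  elongating pol II molecules: %.0f\n"),
    x$n_measured, x$extrapolation_factor, x$total_tr_per_hour,
    x$events_per_min, x$events_per_cycle, x$turnover_per_cycle,
    x$elongating_pols
  ))
  invisible(x)
}

#' Adjust a population-average rate to the active phase of the cycle
#'
#' Genes transcribed only during part of the cell cycle (histone genes in
#' S phase) have an actual rate in the active phase of
#' `tr / phase_fraction`.
#'
#' @param tr Population-average transcription rate (any unit, >= 0).
#' @param phase_fraction Fraction of the cycle in which the gene is
#'   active, in (0, 1].
#' @return Phase-adjusted rate, same unit as `tr`.
#' @export
phase_adjust <- function(tr, phase_fraction) {
  if (any(phase_fraction <= 0) || any(phase_fraction > 1))
    stop("`phase_fraction` must be in (0, 1]")
  tr / phase_fraction
}

#' Polymerase spacing and nucleosome transit timing
#'
#' For a gene transcribed at `tr_per_hour`, successive polymerases pass
#' any point every `3600 / tr_per_hour` seconds; each takes
#' `footprint / speed` seconds to traverse the DNA wrapped by one
#' nucleosome. The remaining fraction of time,
#' `1 - transit / interval`, is available for the nucleosome to stay
#' associated with its DNA.
#'
#' @param tr_per_hour Transcription rate in mRNAs/hour (> 0).
#' @param constants A [kinetic_constants()] object.
#' @return List with `interval_s`, `transit_s`, `occupancy_fraction`.
#' @export
nucleosome_timing <- function(tr_per_hour, constants = kinetic_constants()) {
  if (any(tr_per_hour <= 0)) stop("`tr_per_hour` must be positive")
  interval_s <- 3600 / tr_per_hour
  transit_s <- constants$nucleosome_footprint_bp / constants$elongation_nt_per_s
  list(
    interval_s = interval_s,
    transit_s = transit_s,
    occupancy_fraction = pmax(0, 1 - transit_s / interval_s)
  )
}

#' Census of actively transcribing RNA polymerase II molecules
#'
#' Compares the number of elongating polymerases from the rate table with
#' the pool of hyperphosphorylated, gene-associated pol II molecules.
#' Because some elongating polymerases never yield a mature cytoplasmic
#' mRNA, the productive-event count underestimates the elongating
#' population by up to a factor of two; the census therefore reports the
#' interval `[elongating, 2 * elongating] / phospho_pool` as fractions.
#'
#' @param summary A `snapshot_summary` from [genome_totals()] (or any
#'   list with `elongating_pols`).
#' @param params A [snapshot_params()] object.
#' @return List with `elongating_pols`, `phospho_pool`,
#'   `fraction_low`, `fraction_high` (fractions of the
#'   hyperphosphorylated pool actively transcribing).
#' @export
active_pol_census <- function(summary, params = snapshot_params()) {
  pool <- params$total_polII_per_cell * params$hyperphosphorylated_fraction
  if (pool <= 0) stop("hyperphosphorylated pool is empty")
  e <- summary$elongating_pols
  if (is.null(e) || e < 0) stop("`summary` must carry elongating_pols >= 0")
  list(
    elongating_pols = e,
    phospho_pool = pool,
    fraction_low = e / pool,
    fraction_high = 2 * e / pool
  )
}
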