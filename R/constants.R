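#' Kinetic constants of the exponentially growing yeast cell
#'
#' Bundle of the physiological constants used to convert between
#' transcription rates, polymerase densities and steady-state mRNA
#' abundances. Defaults describe Saccharomyces cerevisiae growing
#' exponentially in rich (YPD) medium.
#'
#' @param doubling_time_min Population doubling time in minutes. Sets the
#'   mRNA dilution rate `ln(2) / doubling_time_min` (1/min).
#' @param total_mrna_per_cell Total mRNA molecules per cell, used for the
#'   transcriptome turnover calculation.
#' @param elongation_nt_per_s RNA polymerase II elongation speed in
#'   nucleotides per second.
#' @param s_phase_fraction Fraction of the cell cycle spent in S phase, the
#'   window in which replication-coupled (histone) genes are transcribed.
#' @param nucleosome_footprint_bp DNA wrapped by one nucleosome, in bp.
#' @param genome_gene_count Number of non-dubious ORFs in the genome, used
#'   to extrapolate totals from the measured gene set.
#'
#' @return An object of class `kinetic_constants` (a named list).
#' @examples
#' kc <- kinetic_constants()
#' kc$doubling_time_min
#' @export
kinetic_constants <- function(doubling_time_min = 113,
                              total_mrna_per_cell = 26000,
                              elongation_nt_per_s = 25,
                              s_phase_fraction = 0.27,
                              nucleosome_footprint_bp = 147L,
                              genome_gene_count = 5796L) {
  stopifnot(
    doubling_time_min > 0, total_mrna_per_cell > 0, elongation_nt_per_s > 0,
    s_phase_fraction > 0, s_phase_fraction <= 1,
    nucleosome_footprint_bp > 0, genome_gene_count > 0
  )
  structure(
    list(
      doubling_time_min = doubling_time_min,
      total_mrna_per_cell = total_mrna_per_cell,
      elongation_nt_per_s = elongation_nt_per_s,
      s_phase_fraction = s_phase_fraction,
      nucleosome_footprint_bp = as.integer(nucleosome_footprint_bp),
      genome_gene_count = as.integer(genome_gene_count)
    ),
    class = "kinetic_constants"
  )
}

#' Elongation speed in kb per minute
#'
#' @param constants A [kinetic_constants()] object.
#' @return Speed in kb/min (default constants give 1.5).
#' @export
elongation_kb_per_min <- function(constants) {
  constants$elongation_nt_per_s * 60 / 1000
}

#' Dilution rate due to cell growth
#'
#' Rate of decrease of mRNA concentration caused by cell volume doubling,
#' `ln(2) / doubling_time` per minute.
#'
#' @inheritParams elongation_kb_per_min
#' @return Dilution rate in 1/min.
#' @export
dilution_rate <- function(constants) {
  log(2) / constants$doubling_time_min
}

#' Parameters of the RNA polymerase II census
#'
#' Cell-biological parameters for the active-polymerase census: how many
#' pol II molecules a cell contains and which fractions are
#' hyperphosphorylated (CTD Ser2/Ser5) and chromatin associated.
#'
#' @param total_polII_per_cell Total RNA pol II molecules per cell.
#' @param hyperphosphorylated_fraction Fraction with hyperphosphorylated CTD.
#' @param chromatin_bound_fraction_low,chromatin_bound_fraction_high Bounds
#'   of the chromatin-associated fraction (FRAP estimates).
#' @return An object of class `snapshot_params`.
#' @export
snapshot_params <- function(total_polII_per_cell = 20000,
                            hyperphosphorylated_fraction = 0.6,
                            chromatin_bound_fraction_low = 0.6,
                            chromatin_bound_fraction_high = 0.8) {
  stopifnot(
    total_polII_per_cell > 0,
    hyperphosphorylated_fraction >= 0, hyperphosphorylated_fraction <= 1,
    chromatin_bound_fraction_low <= chromatin_bound_fraction_high,
    chromatin_bound_fraction_low >= 0, chromatin_bound_fraction_high <= 1
  )
  structure(
    list(
      total_polII_per_cell = total_polII_per_cell,
      hyperphosphorylated_fraction = hyperphosphorylated_fraction,
      chromatin_bound_fraction_low = chromatin_bound_fraction_low,
      chromatin_bound_fraction_high = chromatin_bound_fraction_high
    ),
    class = "snapshot_params"
  )
}
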