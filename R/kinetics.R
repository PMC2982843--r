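#' Calibrate relative abundances to molecules per cell
#'
#' Scales a relative mRNA abundance vector to absolute units using a
#' reference table of absolute abundances (e.g. competitive-PCR
#' measurements). The scale factor is the median, over the `top_k` most
#' abundant reference genes present in both tables, of the ratio
#' reference / relative; median-of-ratios is exactly correct for
#' proportional data and robust otherwise.
#'
#' @param relative_ra Named numeric vector of relative abundances
#'   (arbitrary units, > 0), names are gene ids.
#' @param reference Data frame with columns `gene_id`, `abundance`
#'   (molecules/cell).
#' @param top_k Number of reference-ranked genes used (default 2000).
#' @return Named vector of abundances in molecules/cell, with attribute
#'   `scale_factor`.
#' @export
calibrate_abundance <- function(relative_ra, reference, top_k = 2000L) {
  if (is.null(names(relative_ra))) stop("`relative_ra` must be named by gene")
  common <- reference[reference$gene_id %in% names(relative_ra), , drop = FALSE]
  if (nrow(common) < top_k)
    stop("only ", nrow(common), " genes common to both tables; ",
         "reduce `top_k` (currently ", top_k, ")")
  common <- common[order(-common$abundance, common$gene_id), , drop = FALSE]
  top <- head(common, top_k)
  factor <- median(top$abundance / relative_ra[top$gene_id])
  out <- relative_ra * factor
  attr(out, "scale_factor") <- factor
  out
}

#' mRNA degradation rate from half-life
#'
#' First-order decay: `kd = ln(2) / half_life`. Infinite half-lives give
#' `kd = 0` (perfectly stable message).
#'
#' @param half_life_min Positive half-life in minutes (`Inf` allowed).
#' @return Degradation rate in 1/min.
#' @export
degradation_rate <- function(half_life_min) {
  if (any(!is.na(half_life_min) & half_life_min <= 0))
    stop("half-lives must be positive")
  log(2) / half_life_min
}

#' Indirect transcription rate from steady-state kinetics
#'
#' At steady state in a growing population, synthesis balances the loss of
#' mRNA concentration from degradation and from dilution by cell growth:
#' `tr = ra * kd (+ ra * ln2 / doubling_time)`. Half-life measurements are
#' typically made in non-growing cells, so the dilution term must be added
#' to obtain the rate in exponential growth.
#'
#' @param ra mRNA abundance in molecules/cell (>= 0).
#' @param half_life_min mRNA half-life in minutes (> 0, `Inf` allowed).
#' @param constants A [kinetic_constants()] object.
#' @param include_dilution Add the growth-dilution term `ra * ln2 / T_gen`
#'   (default `TRUE`).
#' @return Indirect transcription rate in molecules/min.
#' @export
indirect_tr <- function(ra, half_life_min, constants = kinetic_constants(),
                        include_dilution = TRUE) {
  if (any(!is.na(ra) & ra < 0)) stop("`ra` must be nonnegative")
  out <- ra * degradation_rate(half_life_min)
  if (include_dilution) out <- out + ra * dilution_rate(constants)
  out
}

#' Calibrate nascent rates from arbitrary units to molecules per minute
#'
#' Converts the bias-corrected run-on signal (arbitrary units,
#' proportional to the nascent transcription rate) into molecules/min
#' using the `top_k` genes with the highest indirect dilution-corrected
#' rate as anchors (their indirect rates are the most confident). The
#' scale factor is the median over the anchors of `ind_tr / tr_au`; ties
#' in the anchor ranking are broken by gene id for determinism.
#'
#' @param tr_au Named vector of nascent rates in arbitrary units (> 0
#'   where used).
#' @param ind_tr Named vector of indirect dilution-corrected rates
#'   (molecules/min), aligned by name with `tr_au` (`NA` allowed).
#' @param top_k Number of anchor genes (default 2000).
#' @return Named vector of nascent rates in molecules/min with attribute
#'   `scale_factor`.
#' @export
calibrate_nascent <- function(tr_au, ind_tr, top_k = 2000L) {
  if (is.null(names(tr_au)) || is.null(names(ind_tr)))
    stop("`tr_au` and `ind_tr` must be named by gene")
  common <- intersect(names(tr_au), names(ind_tr))
  usable <- common[!is.na(tr_au[common]) & !is.na(ind_tr[common]) &
                     tr_au[common] > 0 & ind_tr[common] > 0]
  if (length(usable) < top_k)
    stop("only ", length(usable),
         " genes with positive nascent and indirect rates; need ", top_k)
  anchors <- usable[order(-ind_tr[usable], usable)][seq_len(top_k)]
  factor <- median(ind_tr[anchors] / tr_au[anchors])
  out <- tr_au * factor
  attr(out, "scale_factor") <- factor
  out
}

#' Elongating polymerase density from the transcription rate
#'
#' The flux of elongating polymerases past any point of a gene equals its
#' transcription rate, so the density is `tr / speed` with the speed in
#' kb/min: `density = tr / (elongation_nt_per_s * 60 / 1000)`.
#'
#' @param tr Transcription rate in molecules/min (>= 0).
#' @param constants A [kinetic_constants()] object.
#' @return Density in polymerase molecules per kb.
#' @export
pol_density <- function(tr, constants = kinetic_constants()) {
  tr / elongation_kb_per_min(constants)
}

#' Polymerase molecules per gene
#'
#' @param density_per_kb Polymerase density (molecules/kb, >= 0).
#' @param orf_length_bp ORF length in bp.
#' @return Expected number of elongating polymerase molecules on the gene.
#' @export
pols_per_gene <- function(density_per_kb, orf_length_bp) {
  density_per_kb * orf_length_bp / 1000
}

#' Fraction of transcription devoted to compensating dilution
#'
#' Percentage of a gene's transcription rate needed to offset the loss of
#' mRNA concentration by cell growth, `100 * (ra * ln2 / T_gen) / tr`.
#' Because the dilution demand is computed independently of the nascent
#' rate, raw values can fall outside [0, 100]; they are clamped: over
#' 100% means transcription is dominated by dilution compensation,
#' negative or 0/0 cases map to 0.
#'
#' @param ra mRNA abundance (molecules/cell, >= 0).
#' @param tr Nascent transcription rate (molecules/min, >= 0).
#' @param constants A [kinetic_constants()] object.
#' @return Percentage in [0, 100].
#' @export
dilution_fraction <- function(ra, tr, constants = kinetic_constants()) {
  stopifnot(all(ra >= 0, na.rm = TRUE), all(tr >= 0, na.rm = TRUE))
  demand <- ra * dilution_rate(constants)
  raw <- ifelse(tr > 0, 100 * demand / tr,
                ifelse(demand > 0, 100, 0))
  pmin(100, pmax(0, raw))
}

#' Assemble the per-gene rate table
#'
#' Joins the calibrated nascent rates with abundances, half-lives and
#' derived quantities into the pipeline's main result table.
#'
#' @param catalog Gene catalog (provides `orf_length_bp`).
#' @param tr Named vector of nascent rates (molecules/min).
#' @param tr_au Named vector of nascent rates in arbitrary units.
#' @param ra Named vector of abundances (molecules/cell).
#' @param half_life_min Named vector of half-lives (min).
#' @param constants A [kinetic_constants()] object.
#' @return Data frame with columns `gene_id`, `orf_length_bp`, `tr_au`,
#'   `tr` (molecules/min), `ind_tr_nodil`, `ind_tr` (molecules/min), `ra`
#'   (molecules/cell), `half_life_min`, `density_per_kb`,
#'   `pols_per_gene`, `dilution_pct`. Genes are those with a nascent
#'   rate; kinetic columns are `NA` where abundance or half-life is
#'   missing.
#' @export
rate_table <- function(catalog, tr, tr_au, ra, half_life_min,
                       constants = kinetic_constants()) {
  ids <- names(tr)
  stopifnot(!is.null(ids), all(ids %in% catalog$gene_id))
  len <- catalog$orf_length_bp[match(ids, catalog$gene_id)]
  ra_g <- unname(ra[ids])
  hl_g <- unname(half_life_min[ids])
  dens <- pol_density(unname(tr), constants)
  data.frame(
    gene_id = ids,
    orf_length_bp = len,
    tr_au = unname(tr_au[ids]),
    tr = unname(tr),
    ind_tr_nodil = indirect_tr(ra_g, hl_g, constants, include_dilution = FALSE),
    ind_tr = indirect_tr(ra_g, hl_g, constants, include_dilution = TRUE),
    ra = ra_g,
    half_life_min = hl_g,
    density_per_kb = dens,
    pols_per_gene = pols_per_gene(dens, len),
    dilution_pct = dilution_fraction(ra_g, unname(tr), constants),
    stringsAsFactors = FALSE
  )
}
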