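---
title: "From run-on arrays to absolute nascent transcription rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From run-on arrays to absolute nascent transcription rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentrates)
```

## The problem and the model

Microarray expression data measure mRNA *amounts*. The amount of an mRNA
is, however, the balance of two reactions — synthesis and disappearance —
and the most regulated step for many genes is the nascent transcription
rate (TR): how many transcripts per minute the RNA polymerase II
molecules on a gene actually produce. `nascentrates` converts two array
readouts of polymerase activity in budding yeast into absolute rates:

* **GRO** (genomic run-on): the signal is proportional to the density of
  *elongating* polymerases on each gene, because only active polymerases
  incorporate label during the run-on reaction. It is not strand-specific.
* **RPCC** (RNA pol II ChIP-on-chip): the signal reports the total
  presence of pol II within gene bodies, elongating or not.

Two kinetic identities connect densities, rates and amounts:

1. **Flux.** If elongating polymerases move at speed $v$ (kb/min), the
   number passing the 3' end of a gene per minute — the nascent TR in
   molecules/min — equals the polymerase density $d$ (molecules/kb) times
   $v$, independent of gene length: $TR = d \cdot v$.
2. **Steady state with growth.** In an exponentially growing population
   the mRNA amount per cell $RA$ (molecules/cell) is constant, so
   synthesis balances first-order degradation *and* dilution by cell
   growth:
   $$ TR_{ind} = RA\left(\frac{\ln 2}{t_{1/2}} + \frac{\ln 2}{T_{gen}}\right), $$
   with $t_{1/2}$ the mRNA half-life and $T_{gen}$ the doubling time.
   The dilution term matters: half-lives are measured in non-growing
   cells, so an "indirect TR" computed as $RA \cdot \ln 2 / t_{1/2}$
   alone underestimates the rate that growth demands.

The indirect TR reflects only transcription that yields mature
cytoplasmic mRNA; the nascent TR counts all elongating polymerases,
including those whose transcripts are degraded in the nucleus. The
pipeline exploits the identity where it is most reliable — the genes
with the highest indirect TR — to put the nascent measurements on an
absolute scale, and then uses the *discrepancy* between the two datasets
as biological signal (`ma_lowess_ratio()`, `group_mean_test()`).

## Pipeline stages

1. **Normalization** (`normalize_to_gdna()`): each filter's run-on signal
   is divided by the genomic-DNA hybridization of the same filter,
   cancelling probe amount and length. `scale_arrays()` then equalizes
   array medians (computed on genes measured in every array) so that
   replicates are comparable on a common scale.
2. **Filtering** (`filter_genes()`, `qc_experiments()`): a gene is kept
   if it has a valid measurement in at least 5 of the 8 experiments; an
   experiment is kept if the median Pearson correlation of its log2
   profile with the other experiments reaches 0.7.
3. **Averaging** (`average_experiments()`): replicates are averaged
   within each experiment, then experiment means are averaged — the
   two-stage mean matches the replicate structure and keeps unbalanced
   missingness from overweighting any experiment.
4. **Length-bias correction** (`correct_length_bias()`): see below.
5. **Calibration** (`calibrate_abundance()`, `indirect_tr()`,
   `calibrate_nascent()`): relative mRNA abundances are scaled to
   molecules/cell via the 2000 most abundant reference genes; indirect
   dilution-corrected TRs are computed from abundances and half-lives;
   the corrected run-on signal is scaled to molecules/min via the 2000
   genes with the highest indirect TR. Both calibrations use the
   median-of-ratios estimator: it is scale-equivariant, exactly correct
   for proportional data (the tests assert recovery of the factor to
   1e-12 on noise-free input), and robust to outlying anchors. A fitted
   regression through the origin would weight bright genes more; nothing
   in the procedure requires that, so the simpler estimator is used.
6. **Derived quantities** (`rate_table()`): polymerase density
   $TR / 1.5$ molecules/kb at the default 25 nt/s, polymerases per gene,
   and the percentage of each gene's transcription devoted to
   compensating dilution, clamped to [0, 100] (the dilution demand is
   computed independently of the nascent rate, so raw values can fall
   outside the meaningful range; the clamp marks "all dilution" or
   "negligible dilution").
7. **Snapshot** (`genome_totals()`, `nucleosome_timing()`,
   `active_pol_census()`): genome-wide totals extrapolated by the single
   factor `genome_gene_count / n_measured`, transcription events per
   cell cycle, turnover of the mRNA pool, polymerase spacing versus
   nucleosome transit time, and the fraction of the hyperphosphorylated
   pol II pool that is actually elongating (reported as a 1x–2x interval
   because an unknown share of elongating polymerases never yields a
   mature mRNA).

## The probe-length artifact and its correction

During a run-on reaction each polymerase extends its transcript by only
a short stretch (a few hundred nt). Label therefore accumulates towards
the 3' end of genes: a position $y$ nt from the ORF start can receive
label from polymerases up to $\delta$ nt upstream, so expected coverage
grows linearly until $y = \delta$ and is flat beyond. Integrated over a
probe, the per-gDNA-normalized signal of a full-ORF probe rises with
gene length and saturates, while 3'-terminal probes (used for genes
longer than 3 kb on these arrays) sit entirely in the flat regime. The
result is a signal-versus-length trend with a regime change exactly at
the 3 kb probe-design boundary.

The correction standardizes both GRO and RPCC in log2 space
(`log2_zscore()`; sample standard deviation, n − 1, so that the
standardized values have `sd == 1` exactly), fits separate lowess
smoothers of each signal on ORF length above and below 3 kb (genes of
exactly 3000 bp go to the upper regime, matching the probe rule
"shorter than 3 kb"), subtracts the GRO−RPCC smoother difference, and
reverses the GRO standardization. The RPCC reference retains its own
mild length trend, so the correction removes the probe artifact without
flattening genuine biology. By default the inversion also undoes the
log2 transform (`delog = TRUE`), returning strictly positive arbitrary
units ready for calibration; the log2 scale is available for users who
want to stay in it.

The smoother is Cleveland's lowess: local linear regression, tricube
weights over the `span` nearest neighbours (span 0.2), zero robustness
iterations, evaluated at every observed length (`delta = 0`). Ties in
length get identical neighbourhoods; fitted values are returned in
input order. The test suite checks the fit against a brute-force
weighted-least-squares oracle written directly from the definition
(agreement to 1e-8) rather than trusting one implementation twice.

## The synthetic-data module

No public gene-level truth exists for nascent rates, so the package
ships a generator whose defaults encode the study conditions the
pipeline targets:

| parameter | default | why |
|---|---|---|
| `n_genes` | 5000 | order of the measured yeast gene set |
| `tr_log10_mean` | −0.92 | median TR 0.12 molecules/min (7 mRNAs/h) |
| `tr_log10_sd` | 0.34 | 90% range ≈ 2.3–29.7 mRNAs/h |
| `halflife_log10_mean`, `_sd` | 1.3, 0.25 | median half-life ≈ 20 min, log-normal spread typical of genomic stability datasets |
| `length_log10_mean`, `_sd` | 3.15, 0.25 | median ORF ≈ 1.4 kb, ~10% of genes above 3 kb |
| `runon_extension_nt` | 300 | the labeling extension is "short" but unreported; 300 nt puts the regime change where the probe design changes, and it is a config field, not a claim about the original chemistry |
| `noise_cv` | 0.2 | multiplicative log-normal noise; array signals are positive and heteroscedastic |
| `array_scale_sd` | 0.2 | log-normal array-level intensity factors, removed by median scaling |
| `missing_rate` | 0.05 | uniform missingness, typical spot-failure rate |
| `rpcc_length_bias_exponent` | −0.05 | the ChIP signal decreases slightly with length |
| `n_experiments` × `reps_per_experiment` | 8 × 3 | the 24-sample run-on design |

Ground truth satisfies the steady-state identity by construction
(`ra = tr / (kd + ln2/T_gen)`, asserted to 1e-9 in every truth table),
and the expected run-on signal uses the closed-form labeling integral
(`gro_expected_signal()`), verified against numeric quadrature.

What the simulation does **not** emulate: spatial artifacts and
background on the filters, sequence-dependent labeling efficiency,
cross-hybridization, antisense and intergenic transcription, correlated
(batch) noise, and any real covariance between expression level, length
and half-life. Passing the recovery tests therefore shows the
*arithmetic* of the pipeline is right and that it undoes the biases it
models — not that real arrays contain no other biases.

## Numerical conventions and edge cases

* Standardization uses the sample (n − 1) standard deviation; constant
  or nonpositive inputs are errors, never silently imputed.
* Percentiles use linear interpolation between order statistics
  (R `quantile` type 7), fixed and documented because published summary
  figures are insensitive to the convention at n ≈ 5000.
* Group comparisons default to the Welch unequal-variance t test
  (`var_equal = TRUE` restores the pooled test): gene groups of interest
  are small and their variances differ from the genome background.
* Calibration anchor sets break ties by gene id, making the scale
  factors deterministic.
* Zero or negative signals are treated as missing before any log2 step;
  zero/missing gDNA invalidates the normalized value and is counted in
  the QC report.
* `dilution_fraction()` clamps to [0, 100]; `tr = 0` with `ra > 0` maps
  to 100 ("all dilution"), `ra = 0` to 0.
* All randomness flows from one integer seed through per-stage derived
  streams; equal seeds give byte-identical output TSVs.

## Design choices made where the procedure was open

* The replicate-correlation filter is applied at *experiment* level
  (8 log2 profiles, keep if the median pairwise r ≥ 0.7): the filter
  concerns experiments done in triplicate, and the median is robust to a
  single bad partner. The threshold is an argument, so sample-level
  filtering can be emulated by regrouping arrays.
* Averaging is the two-stage mean on the linear scale after median
  scaling. The original averaging software is proprietary and its exact
  procedure unrecoverable; the two-stage mean respects the experiment
  structure and reduces to the plain mean for balanced complete data
  (asserted in the tests).
* The AU-to-absolute conversions use median-of-ratios rather than a
  fitted line (see stage 5 above).
* Genes missing a half-life get `NA` indirect rates and are excluded
  from calibration; no imputation is attempted.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
default 5000-gene genome with 24 run-on arrays (about a quarter of a
second end to end), use 100-point instances for smoother-oracle
comparisons, and 1000 permutations for the null-calibration check of the
group test. These sizes were chosen so that every property is exercised
at the scale the defaults describe.

## Known limitations

* The elongation speed enters all absolute densities linearly; if pol II
  is faster than 25 nt/s, densities scale down accordingly.
* The census interval inherits every upstream uncertainty (total pol II
  per cell, hyperphosphorylated fraction) multiplicatively.
* The nascent/indirect comparison assumes both datasets refer to the
  same growth state; mixing conditions invalidates the MA correction.
* The pipeline is gene-level: no within-gene polymerase profiles, no
  strand information, no separation of sense from antisense signal.
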