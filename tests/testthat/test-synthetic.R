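test_that("gene catalog applies the probe design rule at the 3 kb boundary", {
  cat <- catalog_from_lengths(c(2999, 3000, 5000, 150))
  # complete ORF below 3 kb
  expect_equal(cat$probe_start_bp[1], 0L)
  expect_equal(cat$probe_end_bp[1], 2999L)
  # 3'-terminal 1 kb at and above 3 kb
  expect_equal(cat$probe_start_bp[2], 2000L)
  expect_equal(cat$probe_end_bp[2], 3000L)
  expect_equal(cat$probe_start_bp[3], 4000L)
  expect_equal(cat$probe_end_bp[3], 5000L)

  gen <- generate_gene_catalog(500, seed = 7)
  expect_true(all(gen$orf_length_bp >= 150))
  short <- gen$orf_length_bp < 3000
  expect_true(all(gen$probe_start_bp[short] == 0))
  expect_true(all((gen$probe_end_bp - gen$probe_start_bp)[!short] == 1000))
  expect_true(all(gen$probe_end_bp[!short] == gen$orf_length_bp[!short]))
  expect_false(anyDuplicated(gen$gene_id) > 0)
})

test_that("gene catalog handles the empty case, rejects negative n, is seeded", {
  empty <- generate_gene_catalog(0)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("gene_id", "orf_length_bp",
                        "probe_start_bp", "probe_end_bp"))
  expect_error(generate_gene_catalog(-1), "nonnegative")
  expect_identical(generate_gene_catalog(100, seed = 3),
                   generate_gene_catalog(100, seed = 3))
  expect_false(identical(generate_gene_catalog(100, seed = 3),
                         generate_gene_catalog(100, seed = 4)))
})

test_that("true kinetics satisfy the steady-state identity with dilution", {
  constants <- kinetic_constants()
  for (seed in 1:5) {
    config <- simulation_config(n_genes = 200, seed = seed)
    catalog <- generate_gene_catalog(200, seed)
    truth <- generate_true_kinetics(catalog, constants, config)
    # RA * (kd + ln2/T_gen) = TR to 1e-9 relative
    expect_lt(max(abs(truth$ra_true * (truth$kd + dilution_rate(constants)) -
                        truth$true_tr) / truth$true_tr), 1e-9)
    expect_equal(truth$kd, log(2) / truth$half_life_min)
    expect_equal(truth$true_density,
                 truth$true_tr / elongation_kb_per_min(constants))
  }
})

test_that("steady-state closed form matches hand-computed values and limits", {
  kc <- kinetic_constants()  # doubling time 113 min
  # tr = 0.12 molecules/min, half-life 20 min: ra = 0.12/(ln2/20 + ln2/113)
  ra <- 0.12 / (log(2) / 20 + dilution_rate(kc))
  expect_equal(ra, 2.9417962, tolerance = 1e-7)
  # and the indirect rate inverts it
  expect_equal(indirect_tr(ra, 20, kc), 0.12, tolerance = 1e-12)
  # dilution-only limit: half-life -> infinity
  ra_stable <- 5 / (log(2) / 1e9 + dilution_rate(kc))
  expect_equal(ra_stable, 5 * 113 / log(2), tolerance = 1e-4)
})

test_that("run-on expected signal matches hand-computed closed forms", {
  # full-ORF probe, L = 2000, delta = 300, d = 1e-4/nt:
  # 1e-4 * (int_0^300 y dy + 300 * 1700) = 1e-4 * 555000 = 55.5
  expect_equal(gro_expected_signal(1e-4, 0, 2000, 300), 55.5)
  # 3'-terminal probe entirely beyond delta: d * delta * probe length
  expect_equal(gro_expected_signal(1e-4, 4000, 5000, 300), 30.0)
  # probe entirely within the ramp
  expect_equal(gro_expected_signal(1e-4, 0, 200, 300), 1e-4 * 200^2 / 2)
  expect_error(gro_expected_signal(1e-4, 0, 2000, 0), "positive")
})

test_that("run-on closed form equals numeric quadrature on random genes", {
  set.seed(11)
  for (i in 1:100) {
    L <- sample(150:8000, 1)
    a <- if (L < 3000) 0 else L - 1000
    d <- runif(1, 1e-6, 1e-3)
    delta <- sample(50:800, 1)
    expect_equal(gro_expected_signal(d, a, L, delta),
                 gro_quadrature_oracle(d, a, L, delta),
                 tolerance = 1e-6)
  }
})

test_that("simulated run-on arrays reproduce expectation and regime change", {
  tt <- toy_truth(lengths = c(200, 1000, 2000, 2999, 3000, 5000, 8000),
                  density_per_kb = rep(0.1, 7))
  config <- quiet_config(n_genes = 7)
  gro <- simulate_gro_arrays(tt$truth, tt$catalog, config)
  gdna <- simulate_gdna_reference(tt$catalog, config)
  norm <- normalize_to_gdna(gro, gdna)$values[, 1]
  # noise-free: per-gDNA signal is non-decreasing in length below 3 kb ...
  expect_true(all(diff(norm[1:4]) > 0))
  # ... and constant at d * delta above (probe start >= delta)
  d_nt <- 0.1 / 1000
  expect_equal(unname(norm[5:7]), rep(d_nt * 300, 3), tolerance = 1e-9)
  # null transcription gives all-zero signals
  tt0 <- toy_truth(c(500, 4000), c(0, 0))
  gro0 <- simulate_gro_arrays(tt0$truth, tt0$catalog,
                              simulation_config(noise_cv = 0.3))
  expect_true(all(gro0$values == 0, na.rm = TRUE))
})

test_that("array simulation is reproducible and layout is as configured", {
  tt <- toy_truth(c(500, 1500, 4000), c(0.05, 0.2, 1))
  config <- simulation_config(seed = 9)
  a <- simulate_gro_arrays(tt$truth, tt$catalog, config)
  b <- simulate_gro_arrays(tt$truth, tt$catalog, config)
  expect_identical(a, b)
  expect_equal(dim(a), c(3L, 24L))
  expect_equal(a$experiment, rep(1:8, each = 3))
  expect_equal(colnames(a$values)[1:4],
               c("exp1_rep1", "exp1_rep2", "exp1_rep3", "exp2_rep1"))
})

test_that("pol II ChIP signal carries the configured length trend", {
  tt <- toy_truth(c(1000, 8000), c(0.3, 0.3))
  # unbiased case: signal proportional to density only
  r0 <- simulate_rpcc_arrays(tt$truth, tt$catalog,
                             quiet_config(rpcc_length_bias_exponent = 0))
  expect_equal(r0$values[1, 1], r0$values[2, 1])
  # default exponent -0.05: ratio 8 kb / 1 kb = 8^(-0.05)
  r1 <- simulate_rpcc_arrays(tt$truth, tt$catalog, quiet_config())
  expect_equal(unname(r1$values[2, 1] / r1$values[1, 1]), 8^(-0.05),
               tolerance = 1e-12)
  # linearity in density
  tt2 <- toy_truth(c(1000, 1000), c(0.3, 0.6))
  r2 <- simulate_rpcc_arrays(tt2$truth, tt2$catalog, quiet_config())
  expect_equal(unname(r2$values[2, 1] / r2$values[1, 1]), 2, tolerance = 1e-12)
})

test_that("genomic DNA reference is proportional to probe length and positive", {
  cat2 <- catalog_from_lengths(c(1000, 2000))
  g <- simulate_gdna_reference(cat2, quiet_config())
  expect_equal(unname(g$values[1, 1] / g$values[2, 1]), 0.5)
  expect_equal(unname(g$values[, 1]), c(1000, 2000))  # unit scale, no noise
  catalog <- catalog_from_lengths(c(300, 2999, 3000, 7000))
  for (seed in 1:100) {
    g <- simulate_gdna_reference(catalog,
                                 simulation_config(seed = seed, noise_cv = 0.5))
    expect_true(all(g$values > 0))
    expect_true(all(!is.na(g$values)))
  }
})

test_that("reference abundances return the most abundant genes", {
  tt <- toy_truth(seq(500, 5000, by = 500), seq(0.1, 1, by = 0.1))
  ref <- simulate_reference_abundances(tt$truth, n_ref = 4, noise_cv = 0)
  top4 <- tt$truth$gene_id[order(-tt$truth$ra_true)][1:4]
  expect_setequal(ref$gene_id, top4)
  expect_equal(ref$abundance,
               tt$truth$ra_true[match(ref$gene_id, tt$truth$gene_id)])
  all10 <- simulate_reference_abundances(tt$truth, n_ref = 10, noise_cv = 0)
  expect_equal(nrow(all10), 10)
  expect_error(simulate_reference_abundances(tt$truth, n_ref = 11), "exceeds")
})

test_that("noisy reference abundances preserve abundance ranks", {
  config <- simulation_config(n_genes = 2000, seed = 5)
  catalog <- generate_gene_catalog(2000, seed = 5)
  truth <- generate_true_kinetics(catalog, kinetic_constants(), config)
  ref <- simulate_reference_abundances(truth, n_ref = 2000, noise_cv = 0.2,
                                       seed = 5)
  rho <- rank_correlation(ref$abundance,
                          truth$ra_true[match(ref$gene_id, truth$gene_id)])
  expect_gt(rho, 0.9)
})
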