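test_that("gDNA normalization divides per array and flags unusable references", {
  s <- sm(matrix(c(10, 6, NA, 8), 2, 2), experiment = c(1L, 2L))
  g <- sm(matrix(c(2, 3, 4, 0), 2, 2), experiment = c(1L, 2L),
          gene_id = rownames(s$values))
  colnames(g$values) <- colnames(s$values)
  out <- normalize_to_gdna(s, g)
  expect_equal(out$values[1, 1], 5)      # 10 / 2
  expect_equal(out$values[2, 1], 2)      # 6 / 3
  expect_true(is.na(out$values[1, 2]))   # missing signal propagates
  expect_true(is.na(out$values[2, 2]))   # zero gDNA -> flagged missing
  expect_equal(attr(out, "n_invalid_gdna"), 1)
  # identical gDNA across genes preserves rank order per array
  s2 <- sm(matrix(runif(20, 1, 10), 10, 2), experiment = c(1L, 2L))
  g2 <- sm(matrix(3, 10, 2), experiment = c(1L, 2L))
  colnames(g2$values) <- colnames(s2$values)
  out2 <- normalize_to_gdna(s2, g2)
  expect_equal(order(out2$values[, 1]), order(s2$values[, 1]))
})

test_that("median scaling equalizes arrays and is idempotent", {
  one <- sm(matrix(c(1, 2, 3, 4, 100), 5, 1))
  expect_equal(median(scale_arrays(one)$values[, 1]), 1)
  # proportional arrays become identical
  v <- matrix(runif(30, 1, 5), 15, 2)
  v[, 2] <- 3 * v[, 1]
  prop <- scale_arrays(sm(v, experiment = c(1L, 2L)))
  expect_equal(prop$values[, 1], prop$values[, 2], ignore_attr = TRUE)
  # idempotence
  set.seed(2)
  m <- sm(matrix(rlnorm(60), 20, 3), experiment = c(1L, 1L, 2L))
  m$values[sample(60, 5)] <- NA
  once <- scale_arrays(m)
  twice <- scale_arrays(once)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  # all-missing column is rejected by the matrix constructor upstream;
  # an array whose complete-gene median is nonpositive is named
  bad <- sm(matrix(c(1, 2, 0, 0), 2, 2), experiment = c(1L, 2L))
  expect_error(scale_arrays(bad), "exp2_rep1")
})

test_that("gene filter counts valid experiments and reports drops", {
  # 8 experiments x 1 replicate; gene 2 valid in only 4 experiments
  v <- matrix(1, 2, 8)
  v[2, 5:8] <- NA
  m <- sm(v, experiment = 1:8)
  res <- filter_genes(m, min_valid = 5)
  expect_equal(res$qc$kept_gene_ids, "g00001")
  expect_equal(res$qc$dropped$gene_id, "g00002")
  expect_equal(res$qc$dropped$reason, "insufficient_valid")
  expect_equal(nrow(res$matrix$values), 1)
  # a gene with one of three replicates present still counts as valid
  v2 <- matrix(NA_real_, 1, 6)
  v2[1, c(1, 4)] <- 2
  m2 <- sm(v2, experiment = rep(1:2, each = 3))
  expect_equal(filter_genes(m2, 2)$qc$kept_gene_ids, "g00001")
  # disabled filter keeps everything; over-strict threshold errors
  expect_equal(length(filter_genes(m, 0)$qc$kept_gene_ids), 2)
  expect_error(filter_genes(m, 9), "exceeds")
})

test_that("qc partitions genes exactly between kept and dropped", {
  set.seed(4)
  v <- matrix(rlnorm(200), 25, 8)
  v[sample(200, 60)] <- NA
  ids <- sprintf("g%05d", 1:25)
  m <- sm(v, experiment = 1:8, gene_id = ids)
  res <- filter_genes(m, 5)
  expect_setequal(c(res$qc$kept_gene_ids, res$qc$dropped$gene_id), ids)
  expect_length(intersect(res$qc$kept_gene_ids, res$qc$dropped$gene_id), 0)
})

test_that("experiment correlation filter drops an uncorrelated experiment", {
  set.seed(8)
  n <- 2000
  base <- rlnorm(n, 0, 1)
  v <- sapply(1:8, function(i) base * rlnorm(n, 0, 0.15))
  v[, 3] <- rlnorm(n, 0, 1)  # experiment 3 replaced by independent noise
  m <- sm(v, experiment = 1:8)
  qc <- qc_experiments(m, min_pearson = 0.7)
  expect_false(3 %in% qc$kept_experiment_ids)
  expect_setequal(qc$kept_experiment_ids, setdiff(1:8, 3))
  expect_true(isSymmetric(qc$pearson))
  expect_equal(unname(diag(qc$pearson)), rep(1, 8))
  # disabled filter keeps everything
  expect_length(qc_experiments(m, min_pearson = -1)$kept_experiment_ids, 8)
  # duplicated experiments correlate perfectly
  dup <- sm(cbind(base, base), experiment = c(1L, 2L))
  qdup <- qc_experiments(dup, 0.7)
  expect_equal(unname(qdup$pearson[1, 2]), 1)
  expect_length(qdup$kept_experiment_ids, 2)
  expect_error(qc_experiments(sm(matrix(base, n, 1)), 0.7), "2 experiments")
})

test_that("two-stage averaging matches hand computation and flat mean", {
  # replicates (2, 4) in experiment 1 and (6) in experiment 2: (3 + 6) / 2
  m <- sm(matrix(c(2, 4, 6), 1, 3), experiment = c(1L, 1L, 2L))
  expect_equal(unname(average_experiments(m)), 4.5)
  # single experiment, single replicate: identity
  one <- sm(matrix(c(1.5, 2.5), 2, 1))
  expect_equal(unname(average_experiments(one)), c(1.5, 2.5))
  # balanced complete design: equals the plain row mean
  set.seed(3)
  v <- matrix(rlnorm(40), 5, 8)
  mb <- sm(v, experiment = rep(1:4, each = 2))
  expect_equal(unname(average_experiments(mb)), unname(rowMeans(v)))
  # only kept experiments contribute
  qc <- qc_report(kept_gene_ids = rownames(v), kept_experiment_ids = c(1L, 2L))
  expect_equal(unname(average_experiments(mb, qc)),
               unname(rowMeans(v[, 1:4])))
})

test_that("averaged synthetic arrays track the expected signal", {
  config <- simulation_config(n_genes = 5000, seed = 2)
  catalog <- generate_gene_catalog(5000, seed = 2)
  truth <- generate_true_kinetics(catalog, kinetic_constants(), config)
  gro <- simulate_gro_arrays(truth, catalog, config)
  avg <- average_experiments(scale_arrays(gro))
  expected <- gro_expected_signal(truth$true_density / 1000,
                                  catalog$probe_start_bp,
                                  catalog$probe_end_bp,
                                  config$runon_extension_nt)
  ok <- is.finite(avg)
  expect_gte(rank_correlation(avg[ok], expected[ok]), 0.95)
})

test_that("normalization and scaling are equivariant to gene order", {
  set.seed(6)
  v <- matrix(rlnorm(60, 0, 1), 20, 3)
  g <- matrix(rlnorm(60, 5, 0.1), 20, 3)
  ids <- sprintf("g%05d", 1:20)
  m <- sm(v, experiment = c(1L, 2L, 3L), gene_id = ids)
  gd <- sm(g, experiment = c(1L, 2L, 3L), gene_id = ids)
  colnames(gd$values) <- colnames(m$values)
  ref <- scale_arrays(normalize_to_gdna(m, gd))
  perm <- sample(20)
  mp <- sm(v[perm, ], experiment = c(1L, 2L, 3L), gene_id = ids[perm])
  gp <- sm(g[perm, ], experiment = c(1L, 2L, 3L), gene_id = ids[perm])
  colnames(gp$values) <- colnames(mp$values)
  out <- scale_arrays(normalize_to_gdna(mp, gp))
  expect_equal(out$values, ref$values[perm, ])
})
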