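test_that("low-count filter keeps a feature alive in any single sample", {
  mat <- rbind(low = c(0L, 2L, 3L), burst = c(0L, 0L, 100L),
               ok = c(10L, 10L, 10L))
  colnames(mat) <- paste0("2nRR_", 1:3)
  out <- filter_low_counts(mat)
  expect_equal(rownames(out), c("burst", "ok"))
  expect_equal(attr(out, "n_removed"), 1L)
  empty <- filter_low_counts(mat[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
})

test_that("TMM factors: identity, scale invariance, and agreement with the reference implementation", {
  set.seed(5)
  mu <- rlnorm(500, log(80), 1)
  a <- rnbinom(500, mu = mu, size = 10)
  mat <- cbind(s1 = a, s2 = a)
  expect_equal(tmm_factors(mat), c(1, 1))
  # doubling a library leaves CPMs equal after normalisation
  mat2 <- cbind(s1 = a + 1L, s2 = 2L * (a + 1L))
  x <- cpm(mat2, tmm_factors(mat2))
  expect_equal(x[, 1], x[, 2], tolerance = 1e-12)
  # planted asymmetric DE: factors match edgeR's published TMM procedure
  b <- rnbinom(500, mu = mu, size = 10)
  b[1:50] <- b[1:50] * 8L
  m3 <- cbind(s1 = a + 1L, s2 = b + 1L, s3 = rnbinom(500, mu = mu, size = 10) + 1L)
  f_ours <- tmm_factors(m3)
  f_edger <- unname(edgeR::calcNormFactors(m3, method = "TMM"))
  expect_equal(f_ours, f_edger, tolerance = 1e-6)
  expect_error(tmm_factors(cbind(a, 0 * a)), "zero library")
})

test_that("the NB exact test finds no DE in identical groups and respects the fold-change gate", {
  set.seed(9)
  mat <- nb_matrix(300, 100, 0.05, n_samples = 6, seed = 9)
  res <- call_de(mat, colnames(mat)[1:3], colnames(mat)[4:6])
  expect_equal(sum(res$is_de), 0L)
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  # strong but small (< 2-fold) shift: significant q yet is_de FALSE
  set.seed(10)
  mu <- rep(2000, 200)
  g1 <- sapply(1:3, function(i) rnbinom(200, mu = 1.6 * mu, size = 1000))
  g2 <- sapply(1:3, function(i) rnbinom(200, mu = mu, size = 1000))
  m <- cbind(g1, g2)
  rownames(m) <- paste0("g", 1:200)
  colnames(m) <- paste0(rep(c("3nR2C", "2nRR"), each = 3), "_", rep(1:3, 2))
  res2 <- call_de(m, colnames(m)[1:3], colnames(m)[4:6])
  gated <- res2$q_value < 0.05 & abs(res2$log2fc) <= 1
  expect_gt(sum(gated), 0)
  expect_false(any(res2$is_de[gated]))
})

test_that("an 8-fold change with 3v3 replicates is detected almost always", {
  set.seed(13)
  hits <- 0L
  n_true <- 20
  for (rep in 1:3) {
    mu <- rlnorm(400, log(100), 0.5)
    mu1 <- mu
    mu1[seq_len(n_true)] <- 8 * mu1[seq_len(n_true)]  # DE features in a null background
    m <- cbind(sapply(1:3, function(i) rnbinom(400, mu = mu1, size = 20)),
               sapply(1:3, function(i) rnbinom(400, mu = mu, size = 20)))
    rownames(m) <- paste0("g", seq_len(400))
    colnames(m) <- paste0(rep(c("3nR2C", "2nRR"), each = 3), "_", rep(1:3, 2))
    res <- call_de(m, colnames(m)[1:3], colnames(m)[4:6])
    hits <- hits + sum(res$is_de[seq_len(n_true)])
  }
  expect_gte(hits / (3 * n_true), 0.95)
})

test_that("dosage scaling verdicts: exact compensation reads lower/equal/higher", {
  set.seed(17)
  y <- rlnorm(500, log(300), 1)   # parent CPM
  x <- y / 2                      # exactly compensated triploid subgenome
  res <- dosage_scaling_test(x, y)
  expect_equal(res$verdict, c("lower", "equal", "higher"))
  expect_lt(res$p_value[res$scale == 1], 0.01)
  expect_gt(res$p_value[res$scale == 2], 0.05)
  # paired mode degenerates gracefully on identical values
  resp <- dosage_scaling_test(x, y, mode = "paired")
  expect_equal(resp$verdict, c("lower", "equal", "higher"))
  expect_equal(resp$p_value[resp$scale == 2], 1)
  expect_error(dosage_scaling_test(1:5, 1:5), "at least 10")
})

test_that("verdicts are monotone in the scale under any proportional model", {
  set.seed(19)
  y <- rlnorm(400, log(200), 1)
  for (rho in c(0.3, 0.5, 0.8, 1.2)) {
    v <- dosage_scaling_test(rho * y, y, scales = c(0.25, 0.5, 1, 2, 4))$verdict
    ord <- c(lower = 1, equal = 2, higher = 3)
    expect_true(all(diff(ord[v]) >= 0))
  }
})

test_that("the x2 test recovers the compensated generating model on simulated counts", {
  sc <- tiny_scenario(seed = 23, n_chrom_pairs = 5, genes_per_chrom = 80,
                      cpgs_per_promoter = 1, cpgs_per_body = 0,
                      n_recombined_genes = 0,
                      compensation_mode = "compensated")
  design <- sim_design(sc)
  counts <- simulate_expression(design)
  md <- attr(counts, "metadata")
  cpm0 <- cpm(counts, rep(1, ncol(counts)))
  x <- rowMeans(cpm0[design$pairs$gene_R,
                     md$sample[md$genotype == "3nR2C"]])
  y <- rowMeans(cpm0[design$pairs$gene_R,
                     md$sample[md$genotype == "2nRR"]])
  res <- dosage_scaling_test(x, y)
  expect_equal(res$verdict, c("lower", "equal", "higher"))
  # the uncompensated model instead reads equal at x1 for the duplicated subgenome
  sc2 <- tiny_scenario(seed = 23, n_chrom_pairs = 5, genes_per_chrom = 80,
                       cpgs_per_promoter = 1, cpgs_per_body = 0,
                       n_recombined_genes = 0,
                       compensation_mode = "uncompensated")
  d2 <- sim_design(sc2)
  c2 <- simulate_expression(d2)
  cp <- cpm(c2, rep(1, ncol(c2)))
  x2 <- rowMeans(cp[d2$pairs$gene_R, md$sample[md$genotype == "3nR2C"]])
  y2 <- rowMeans(cp[d2$pairs$gene_R, md$sample[md$genotype == "2nRR"]])
  r2 <- dosage_scaling_test(x2, y2)
  expect_equal(r2$verdict[r2$scale == 2], "higher")
})
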