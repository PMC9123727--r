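test_that("spike-in error rate is the pooled count ratio, with contract errors", {
  lam <- cyt("lambda", c(1, 2), c(5, 0), c(495, 500),
             context = c("CpG", "CHH"))
  expect_equal(estimate_error_rate(lam), 0.005)
  expect_equal(estimate_error_rate(cyt("lambda", 1, 0, 100)), 0)
  expect_warning(r <- estimate_error_rate(cyt("lambda", 1, 20, 80)),
                 "conversion")
  expect_equal(r, 0.2)
  expect_error(estimate_error_rate(cyt("lambda", 1, 0, 0)), "zero total")
})

test_that("binomial caller matches a brute-force tail oracle for n <= 30", {
  err <- 0.0137
  grid <- do.call(rbind, lapply(1:30, function(n)
    data.frame(n = n, k = 0:n)))
  rec <- cyt("c", seq_len(nrow(grid)), grid$k, grid$n - grid$k)
  calls <- call_methylation(rec, err, min_coverage = 1)
  # oracle: P(X >= k) by direct summation of the binomial pmf
  oracle <- mapply(function(n, k) sum(stats::dbinom(k:n, n, err)),
                   grid$n, grid$k)
  expect_equal(calls$p_value, oracle, tolerance = 1e-12)
  # k = 0 always gives p = 1; a fully methylated deep site is tiny
  expect_equal(calls$p_value[calls$n_meth == 0], rep(1, 30))
  full <- call_methylation(cyt("c", 1, 10, 0), 0.005, min_coverage = 5)
  expect_equal(full$p_value, 0.005^10, tolerance = 1e-12)
})

test_that("coverage below the threshold is never called methylated", {
  rec <- cyt("c", 1:2, c(4L, 10L), c(0L, 0L))
  calls <- call_methylation(rec, 0.005, min_coverage = 5)
  expect_false(calls$is_methylated[1])   # coverage 4 < 5
  expect_true(is.na(calls$q_value[1]))
  expect_true(calls$is_methylated[2])
})

test_that("region level: coverage vs site weighting", {
  rec <- cyt("c", c(10, 20), c(5, 0), c(5, 10))
  expect_equal(region_level(rec, "c", 1, 100, "coverage"), 0.25)
  expect_equal(region_level(rec, "c", 1, 100, "site"), 0.25)
  # uneven coverage makes the weighting matter
  rec2 <- cyt("c", c(10, 20), c(9, 0), c(1, 90))
  expect_equal(region_level(rec2, "c", 1, 100, "coverage"), 0.09)
  expect_equal(region_level(rec2, "c", 1, 100, "site"), 0.45)
  expect_true(is.na(region_level(rec2, "c", 200, 300)))
})

mk_gene <- function(gene_id = "g1", chrom = "c", strand = "+",
                    exons = cbind(start = c(3001, 3501, 4201),
                                  end = c(3300, 3800, 4600))) {
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  start <- min(exons)
  end <- max(exons)
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             tss = if (strand == "-") end else start,
             tts = if (strand == "-") start else end,
             start = start, end = end, subgenome = "R",
             exons = I(list(exons)), stringsAsFactors = FALSE)
}

test_that("binned profiles are flat for uniform methylation and strand-aware", {
  g <- mk_gene()
  pos <- seq(1001, 6600, by = 7)
  rec <- cyt("c", pos, 7L, 3L)       # uniform level 0.7 everywhere
  prof <- binned_profile(rec, g)
  expect_equal(nrow(prof), 8 * 20)
  expect_true(all(abs(prof$level[!is.na(prof$level)] - 0.7) < 1e-12))

  # minus-strand gene: bin 1 of the upstream flank is at coordinates > tss
  gm <- mk_gene(strand = "-")
  hot <- cyt("c", gm$tss + 1901:2000, 10L, 0L)      # 5'-most 100 bp of Up2k
  cold <- cyt("c", gm$tss + 1:100, 0L, 10L)
  prof2 <- binned_profile(rbind(hot, cold), gm)
  up <- prof2[prof2$region == "Up2k", ]
  expect_equal(up$level[up$bin == 1], 1)    # far side = bin 1
  expect_equal(up$level[up$bin == 20], 0)   # TSS-proximal side = bin 20
})

test_that("flank bins are 100 bp and element profiles pool genes coverage-weighted", {
  g <- mk_gene()
  # one covered site per Up2k bin boundary start: bins are 100 bp
  pos <- g$start - 2000 + (0:19) * 100
  rec <- cyt("c", pos, 10L, 0L)
  prof <- binned_profile(rec, g)
  up <- prof[prof$region == "Up2k", ]
  expect_equal(up$n_meth, rep(10, 20))   # exactly one site lands per bin
  # two genes, one fully methylated and one unmethylated but deeper:
  g2 <- mk_gene(gene_id = "g2", chrom = "d")
  rec2 <- rbind(cyt("c", g$start + 10, 5L, 0L),
                cyt("d", g2$start + 10, 0L, 15L))
  prof2 <- binned_profile(rec2, rbind(g, g2))
  fe <- prof2[prof2$region == "first_exon" & prof2$bin == 1, ]
  expect_equal(fe$level, 0.25)           # 5 / 20, coverage-weighted
})

test_that("TE profiles cover body and both flanks", {
  te <- data.frame(chrom = "c", start = 5001, end = 5800, strand = "+",
                   stringsAsFactors = FALSE)
  rec <- rbind(cyt("c", seq(3001, 5000, 13), 9L, 1L),   # upstream flank 0.9
               cyt("c", seq(5001, 5800, 13), 5L, 5L),   # body 0.5
               cyt("c", seq(5801, 7800, 13), 1L, 9L))   # downstream 0.1
  prof <- te_methylation(rec, te)
  lv <- tapply(prof$n_meth, prof$region, sum) /
    tapply(prof$n_meth + prof$n_unmeth, prof$region, sum)
  expect_equal(as.numeric(lv[c("TE_flank_up", "TE_body", "TE_flank_down")]),
               c(0.9, 0.5, 0.1))
})

test_that("window DMR test matches a hypergeometric oracle and merges runs", {
  # identical groups: no DMRs
  r <- cyt("c", c(10, 30, 50, 70), 5L, 5L)
  expect_equal(nrow(call_dmrs(list(r), list(r))), 0L)

  # planted window: pooled 50/50 vs 5/95 over >= 4 CpGs
  g1 <- cyt("c", c(10, 30, 50, 70), c(13L, 12L, 13L, 12L), c(12L, 13L, 12L, 13L))
  g2 <- cyt("c", c(10, 30, 50, 70), c(1L, 1L, 1L, 2L), c(24L, 24L, 24L, 23L))
  dmr <- call_dmrs(list(g1), list(g2), window_bp = 100)
  expect_equal(nrow(dmr), 1L)
  expect_equal(dmr$delta, 0.45)
  # oracle: two-sided Fisher p by enumerating the hypergeometric support
  ps <- stats::dhyper(0:55, 55, 145, 100)
  p_oracle <- sum(ps[ps <= ps[51] * (1 + 1e-7)])
  expect_lt(p_oracle, 1e-10)
  expect_equal(stats::fisher.test(matrix(c(50, 50, 5, 95), 2))$p.value,
               p_oracle, tolerance = 1e-9)

  # two adjacent significant windows merge into one record
  g1b <- rbind(g1, cyt("c", c(110, 130, 150, 170), 13L, 12L))
  g2b <- rbind(g2, cyt("c", c(110, 130, 150, 170), 1L, 24L))
  dmr2 <- call_dmrs(list(g1b), list(g2b), window_bp = 100)
  expect_equal(nrow(dmr2), 1L)
  expect_equal(dmr2$start, 1L)
  expect_equal(dmr2$end, 200L)
})

test_that("raising min_delta never increases the DMR count", {
  set.seed(42)
  pos <- sort(sample(1:5000, 400))
  lev <- stats::runif(400)
  g1 <- lapply(1:2, function(i)
    cyt("c", pos, stats::rbinom(400, 30, lev), 30L - stats::rbinom(400, 30, lev)))
  lev2 <- pmin(1, lev + ifelse(pos < 2500, 0.4, 0))
  g2 <- lapply(1:2, function(i)
    cyt("c", pos, stats::rbinom(400, 30, lev2), 30L - stats::rbinom(400, 30, lev2)))
  # count significant windows (merged spans / window size): merging makes
  # the number of merged records non-monotone, the window count is not
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4), function(d) {
    dmr <- call_dmrs(g1, g2, min_delta = d)
    sum((dmr$end - dmr$start + 1) / 100)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("replicate pooling sums counts per site", {
  a <- cyt("c", c(1, 5), c(2, 3), c(8, 7))
  b <- cyt("c", c(5, 9), c(1, 4), c(9, 6))
  p <- pool_replicates(list(a, b))
  expect_equal(p$pos, c(1L, 5L, 9L))
  expect_equal(p$n_meth, c(2L, 4L, 4L))
  expect_equal(p$n_unmeth, c(8L, 16L, 6L))
})

test_that("promoter levels are strand-aware 2 kb windows upstream of the TSS", {
  g <- mk_gene()                      # + strand, tss 3001
  gm <- mk_gene(gene_id = "gm", strand = "-")  # tss 4600
  rec <- rbind(cyt("c", 2500, 8L, 2L),   # in g's promoter [1001, 3000]
               cyt("c", 5000, 1L, 9L))   # in gm's promoter [4601, 6600]
  lv <- promoter_levels(rec, rbind(g, gm))
  expect_equal(unname(lv["g1"]), 0.8)
  expect_equal(unname(lv["gm"]), 0.1)
})
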