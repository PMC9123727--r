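test_that("analytic reference lines and boundaries reproduce the printed values", {
  expect_equal(expected_log_ratio(2, 1), 0.30103, tolerance = 1e-5)
  expect_equal(expected_log_ratio(1, 2), -0.30103, tolerance = 1e-5)
  expect_equal(expected_log_ratio(1, 1), 0)
  b <- default_boundaries(2, 1)
  expect_equal(b$lower, 0, tolerance = 1e-10)
  expect_equal(b$upper, 0.60206, tolerance = 1e-5)
  b2 <- default_boundaries(1, 2)
  expect_equal(b2$lower, -0.60206, tolerance = 1e-5)
  expect_equal(b2$upper, 0, tolerance = 1e-10)
  b3 <- default_boundaries(1, 1)
  expect_equal(b3$lower, -b3$upper)
  expect_error(expected_log_ratio(0, 1), "positive")
})

test_that("read-ratio calls: arithmetic, filters, one-sided channel", {
  pairs <- data.frame(
    reads_R = c(200L, 500L, 5L, 90L, 0L),
    reads_C = c(100L, 100L, 3L, 0L, 60L),
    len_R = c(1000, 1000, 1000, 1500, 1000),
    len_C = c(1000, 1000, 1000, 1500, 1000))
  hr <- call_hr(pairs, "3nR2C")
  expect_equal(hr$log_ratio[1], log10(2), tolerance = 1e-12)
  expect_false(hr$flagged[1])                      # on the reference line
  expect_equal(hr$log_ratio[2], log10(5), tolerance = 1e-12)
  expect_true(hr$flagged[2])                       # 0.699 > 0.60206
  expect_true(is.na(hr$log_ratio[3]))              # below min_reads
  expect_false(hr$flagged[3])
  expect_true(is.na(hr$log_ratio[4]) && hr$one_sided[4])  # zero C side
  expect_true(hr$one_sided[5])
  expect_true(all(hr$expected > hr$lower & hr$expected < hr$upper))
  expect_error(call_hr(data.frame(reads_R = -1L, reads_C = 1L,
                                  len_R = 1, len_C = 1), "3nR2C"),
               "negative")
})

test_that("swapping subgenomes negates the statistic and mirrors the band", {
  set.seed(7)
  pairs <- data.frame(reads_R = rpois(50, 150), reads_C = rpois(50, 80),
                      len_R = sample(800:2000, 50), len_C = sample(800:2000, 50))
  a <- call_hr(pairs, copy_R = 2, copy_C = 1)
  sw <- data.frame(reads_R = pairs$reads_C, reads_C = pairs$reads_R,
                   len_R = pairs$len_C, len_C = pairs$len_R)
  b <- call_hr(sw, copy_R = 1, copy_C = 2)
  expect_equal(b$log_ratio, -a$log_ratio)
  expect_equal(b$expected, -a$expected)
  expect_equal(b$lower, -a$upper)
  expect_equal(b$upper, -a$lower)
  expect_equal(b$flagged, a$flagged)
})

test_that("trend line matches an independent weighted-least-squares oracle", {
  set.seed(12)
  x <- sort(runif(60, 0, 1e6))
  y <- 0.3 + sin(x / 2e5) * 0.1 + rnorm(60, 0, 0.02)
  tr <- trend_line(x, y, span = 0.4)
  # oracle at an interior point: same tricube neighbourhood, fit via lm()
  i <- 31
  x0 <- tr$position[i]
  q <- floor(0.4 * 60)
  d <- abs(x - x0)
  h <- sort(d)[q]
  w <- pmax(0, (1 - pmin(1, d / h)^3)^3)
  fit <- lm(y ~ x, weights = w)
  expect_equal(tr$trend[i], unname(predict(fit, data.frame(x = x0))),
               tolerance = 1e-8)
  # constant input -> constant trend
  tc <- trend_line(x, rep(0.25, 60))
  expect_equal(tc$trend, rep(0.25, 60))
  # exactly linear input is reproduced for any span
  tl <- trend_line(x, 2 + 3e-7 * x, span = 1)
  expect_equal(tl$trend, 2 + 3e-7 * tl$position, tolerance = 1e-10)
  expect_error(trend_line(1:5, 1:5), "at least 10")
})

test_that("planted one-copy exchanges are recovered with high recall and low FPR", {
  sc <- tiny_scenario(seed = 41, n_chrom_pairs = 5, genes_per_chrom = 100,
                      n_recombined_genes = 40, cpgs_per_promoter = 1,
                      cpgs_per_body = 0, depth_per_copy = 30)
  design <- sim_design(sc)
  reseq <- simulate_reseq(design)
  truth <- design$pairs
  for (g in c("3nR2C", "3nRC2")) {
    hr <- call_hr(reseq[[g]], g)
    detected <- hr$flagged | hr$one_sided
    recall <- mean(detected[truth$recombined])
    fpr <- mean(detected[!truth$recombined])
    expect_gte(recall, 0.9)
    expect_lte(fpr, 0.05)
  }
})

test_that("unrecombined pairs centre on the analytic reference line", {
  sc <- tiny_scenario(seed = 43, n_chrom_pairs = 4, genes_per_chrom = 100,
                      n_recombined_genes = 0, cpgs_per_promoter = 1,
                      cpgs_per_body = 0)
  design <- sim_design(sc)
  hr <- call_hr(simulate_reseq(design)[["3nR2C"]], "3nR2C")
  expect_equal(mean(hr$log_ratio, na.rm = TRUE), log10(2), tolerance = 0.01)
})
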