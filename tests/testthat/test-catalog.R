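mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query = r[[1]], subject = r[[2]],
               identity = as.numeric(r[[3]]), aln_len = as.integer(r[[4]]),
               evalue = as.numeric(r[[5]]), bitscore = as.numeric(r[[6]]),
               q_cov = as.numeric(r[[7]]), stringsAsFactors = FALSE)
  }))
}

test_that("reciprocal best hits enforce all filters and reciprocity", {
  # mutual best, everything passes
  rc <- mk_hits(list("A", "B", 95, 400, 1e-50, 500, 0.9))
  cr <- mk_hits(list("B", "A", 95, 400, 1e-50, 500, 0.9))
  expect_equal(reciprocal_best_hits(rc, cr),
               data.frame(gene_R = "A", gene_C = "B",
                          stringsAsFactors = FALSE))

  # alignment shorter than the 300 bp identity-length threshold -> dropped
  rc2 <- mk_hits(list("A", "B", 95, 250, 1e-50, 500, 0.9))
  cr2 <- mk_hits(list("B", "A", 95, 250, 1e-50, 500, 0.9))
  expect_equal(nrow(reciprocal_best_hits(rc2, cr2)), 0L)

  # A's best is B but B's best is A2 -> A-B dropped (A2-B is reciprocal)
  rc3 <- mk_hits(list("A", "B", 95, 400, 1e-50, 500, 0.9),
                 list("A2", "B", 95, 400, 1e-50, 400, 0.9))
  cr3 <- mk_hits(list("B", "A2", 95, 400, 1e-50, 600, 0.9),
                 list("B", "A", 95, 400, 1e-50, 500, 0.9))
  rbh3 <- reciprocal_best_hits(rc3, cr3)
  expect_equal(rbh3$gene_R, "A2")
  expect_false("A" %in% rbh3$gene_R)

  # coverage and e-value thresholds
  rc4 <- mk_hits(list("A", "B", 95, 400, 1e-50, 500, 0.75))
  expect_equal(nrow(reciprocal_best_hits(rc4, cr)), 0L)
  rc5 <- mk_hits(list("A", "B", 95, 400, 1e-4, 500, 0.9))
  expect_equal(nrow(reciprocal_best_hits(rc5, cr)), 0L)

  # empty input -> empty output
  expect_equal(nrow(reciprocal_best_hits(rc[0, ], cr[0, ])), 0L)
})

test_that("greedy chromosome vote maximises total votes and breaks ties lexicographically", {
  pairs <- data.frame(
    chrom_R = c(rep("r1", 12), rep("r2", 8)),
    chrom_C = c(rep("c1", 10), rep("c2", 2), rep("c2", 8)),
    stringsAsFactors = FALSE)
  ocp <- assign_orthologous_chromosomes(pairs)
  expect_equal(ocp, c(r1 = "c1", r2 = "c2"))

  # independent brute-force oracle: enumerate all one-to-one matchings
  votes <- table(pairs$chrom_R, pairs$chrom_C)
  perms <- list(c(1, 2), c(2, 1))
  scores <- vapply(perms, function(p)
    sum(votes[cbind(1:2, p)]), numeric(1))
  best <- perms[[which.max(scores)]]
  expect_equal(unname(ocp[rownames(votes)]), colnames(votes)[best])

  # tie broken lexicographically by (chrom_R, chrom_C)
  tie <- data.frame(chrom_R = rep("r1", 10),
                    chrom_C = rep(c("c1", "c2"), each = 5),
                    stringsAsFactors = FALSE)
  expect_equal(assign_orthologous_chromosomes(tie), c(r1 = "c1"))

  single <- data.frame(chrom_R = "r9", chrom_C = "c3",
                       stringsAsFactors = FALSE)
  expect_equal(assign_orthologous_chromosomes(single), c(r9 = "c3"))
})

test_that("catalogue keeps only OCP-consistent pairs and sets copy numbers", {
  pairs <- data.frame(gene_R = c("a1", "a2"), gene_C = c("b1", "b2"),
                      chrom_R = c("r1", "r1"), chrom_C = c("c1", "c2"),
                      stringsAsFactors = FALSE)
  cat <- build_catalog(pairs, c(r1 = "c1"))
  expect_equal(cat$gene_R, "a1")
  expect_equal(cat$ocp_id, "r1:c1")
  expect_equal(cat$copy_R_3nR2C, 2L)
  expect_equal(cat$copy_C_3nR2C, 1L)
  expect_equal(cat$copy_R_3nRC2, 1L)
  expect_equal(cat$copy_C_3nRC2, 2L)
  expect_equal(cat$copy_R_2nRR, 2L)
  expect_equal(cat$copy_C_2nRR, 0L)
})

test_that("catalogue recall is 1 on a simulated complex with planted orthology", {
  sim <- simulate_complex(tiny_scenario(seed = 21), tempfile("simcat"))
  f <- sim$files
  rc <- read_hit_table(f$hits_RtoC, f$lengths)
  cr <- read_hit_table(f$hits_CtoR, f$lengths)
  genes <- read_gene_annotation(f$genes, "gff3")
  rbh <- add_pair_chromosomes(reciprocal_best_hits(rc, cr), genes)
  cat <- build_catalog(rbh, assign_orthologous_chromosomes(rbh))
  truth <- sim$truth$genes
  got <- paste(cat$gene_R, cat$gene_C)
  expect_true(all(paste(truth$gene_R, truth$gene_C) %in% got))
  # partial matching: injective both ways
  expect_false(anyDuplicated(cat$gene_R) > 0)
  expect_false(anyDuplicated(cat$gene_C) > 0)
})
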