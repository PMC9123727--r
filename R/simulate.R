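# Synthetic allotriploid complex generator. Emits a fully labelled
# in-silico version of the study design (2nRR, 2nCC, 3nR2C, 3nRC2; three
# replicates each): per-CpG methylation counts with a lambda spike-in,
# homoeolog expression counts under a configurable dosage model,
# resequencing depth with planted recombination events, reciprocal hit
# tables encoding the true orthology, and miRNA loci in the six
# copy-number patterns.

#' Simulation scenario for the in-silico allotriploid complex
#'
#' All study conditions live here. Methylation counts are beta-binomial
#' (coverage Poisson, per-site success probability Beta around the planted
#' mean with the given precision) so replicates are realistically
#' overdispersed; expression counts are negative binomial with means set by
#' the dosage model; resequencing reads are Poisson in the per-gene copy
#' number.
#'
#' @param seed RNG seed; everything downstream is a deterministic function
#'   of the scenario.
#' @param n_chrom_pairs,genes_per_chrom genome layout; total pairs is their
#'   product.
#' @param cpgs_per_promoter,cpgs_per_body CpG sites simulated per promoter
#'   (2 kb upstream) and per gene body; the 2 kb downstream flank also
#'   receives \code{cpgs_per_body} sites at the gene-body level.
#' @param parent_meth_divergence per-gene target |parental promoter
#'   methylation difference| in \[0,1\]; scalar or vector recycled over
#'   genes, or \code{NULL} for the default mixture (55 percent drawn in
#'   \[0,0.4), 25 percent in \[0.4,0.6), 20 percent in \[0.62,0.95)), which
#'   yields hyper-, hypo- and non-DMG strata.
#' @param constant_methylation if non-\code{NULL}, every simulated cytosine
#'   (promoters, bodies, TEs) gets this methylation mean in every genotype;
#'   used for profile-flatness checks.
#' @param beta_binomial_precision precision (a+b) of the per-site Beta;
#'   larger is less overdispersed.
#' @param mean_coverage mean per-site read coverage (Poisson).
#' @param compensation_mode \code{"compensated"} (each subgenome expressed
#'   at half its parental per-two-copy mean, so doubling recovers the
#'   parent), \code{"uncompensated"} (expression proportional to copy
#'   number) or \code{"partial"} (interpolated by \code{alpha}).
#' @param alpha degree of compensation in \[0,1\] for
#'   \code{compensation_mode = "partial"} (1 = fully compensated).
#' @param mean_expression,expression_sdlog log-normal parental per-two-copy
#'   expression means.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param n_recombined_genes number of pairs with a planted promoter
#'   exchange (inherited by both triploids; shifts one resequencing copy
#'   towards the donor subgenome).
#' @param depth_per_copy resequencing reads per copy per kb.
#' @param mirna_pattern_counts named integer vector over
#'   P1,P2,P3,P4,P5R,P5C,P6R,P6C; the defaults are the six-pattern counts
#'   observed in the carp complex.
#' @param mirna_mean_expression mean per-locus miRNA expression.
#' @param error_rate_lambda bisulfite non-conversion error planted on the
#'   unmethylated lambda spike-in contig, in (0, 0.05).
#' @param n_lambda_sites cytosines simulated on the spike-in contig.
#' @param body_methylation gene-body methylation mean (all genotypes).
#' @param te_methylation_level transposon methylation mean.
#' @param n_te_per_chrom transposon intervals per chromosome.
#' @param n_replicates biological replicates per genotype.
#' @return an object of class \code{sim_scenario}.
#' @export
sim_scenario <- function(seed = 1L,
                         n_chrom_pairs = 4L,
                         genes_per_chrom = 60L,
                         cpgs_per_promoter = 15L,
                         cpgs_per_body = 10L,
                         parent_meth_divergence = NULL,
                         constant_methylation = NULL,
                         beta_binomial_precision = 50,
                         mean_coverage = 20,
                         compensation_mode = c("compensated",
                                               "uncompensated", "partial"),
                         alpha = 1,
                         mean_expression = 100,
                         expression_sdlog = 1,
                         nb_dispersion = 0.05,
                         n_recombined_genes = 20L,
                         depth_per_copy = 30,
                         mirna_pattern_counts = c(P1 = 114L, P2 = 65L,
                                                  P3 = 34L, P4 = 51L,
                                                  P5R = 26L, P5C = 6L,
                                                  P6R = 133L, P6C = 69L),
                         mirna_mean_expression = 50,
                         error_rate_lambda = 0.005,
                         n_lambda_sites = 300L,
                         body_methylation = 0.7,
                         te_methylation_level = 0.9,
                         n_te_per_chrom = 4L,
                         n_replicates = 3L) {
  compensation_mode <- match.arg(compensation_mode)
  stopifnot(n_chrom_pairs >= 1L, genes_per_chrom >= 1L,
            cpgs_per_promoter >= 1L, cpgs_per_body >= 0L,
            beta_binomial_precision > 0, mean_coverage > 0,
            alpha >= 0, alpha <= 1, nb_dispersion > 0,
            depth_per_copy > 0, n_lambda_sites >= 1L, n_replicates >= 1L,
            error_rate_lambda > 0, error_rate_lambda < 0.05)
  n_pairs <- n_chrom_pairs * genes_per_chrom
  if (n_recombined_genes > n_pairs) {
    stop("n_recombined_genes (", n_recombined_genes,
         ") exceeds the total number of pairs (", n_pairs, ")")
  }
  if (!all(names(mirna_pattern_counts) %in% MIRNA_PATTERNS)) {
    stop("mirna_pattern_counts names must be among: ",
         paste(MIRNA_PATTERNS, collapse = ", "))
  }
  out <- as.list(environment())
  out$n_pairs <- n_pairs
  structure(out, class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Allotriploid simulation scenario\n")
  cat(sprintf("  seed %d | %d chromosome pairs x %d genes = %d homoeolog pairs\n",
              x$seed, x$n_chrom_pairs, x$genes_per_chrom, x$n_pairs))
  cat(sprintf("  dosage model: %s%s | NB dispersion %.3g\n",
              x$compensation_mode,
              if (x$compensation_mode == "partial")
                sprintf(" (alpha = %.2f)", x$alpha) else "",
              x$nb_dispersion))
  cat(sprintf("  methylation: %d promoter + %d body CpGs/gene, coverage %.3g, precision %.3g\n",
              x$cpgs_per_promoter, x$cpgs_per_body, x$mean_coverage,
              x$beta_binomial_precision))
  cat(sprintf("  %d recombined pairs | reseq depth %.3g reads/copy/kb | lambda error %.4f\n",
              x$n_recombined_genes, x$depth_per_copy, x$error_rate_lambda))
  cat(sprintf("  miRNAs: %d across %d patterns | replicates %d\n",
              sum(x$mirna_pattern_counts), length(x$mirna_pattern_counts),
              x$n_replicates))
  invisible(x)
}

# sample the per-gene target |parental divergence|
.draw_divergence <- function(scenario, n) {
  if (!is.null(scenario$parent_meth_divergence)) {
    return(rep_len(scenario$parent_meth_divergence, n))
  }
  stratum <- sample(c("low", "mid", "high"), n, replace = TRUE,
                    prob = c(0.55, 0.25, 0.20))
  d <- numeric(n)
  d[stratum == "low"] <- stats::runif(sum(stratum == "low"), 0, 0.4)
  d[stratum == "mid"] <- stats::runif(sum(stratum == "mid"), 0.4, 0.6)
  d[stratum == "high"] <- stats::runif(sum(stratum == "high"), 0.62, 0.95)
  d
}

#' Deterministic design (layout + ground truth) for a scenario
#'
#' Lays out chromosomes, gene models and CpG sites, and draws every latent
#' truth value (methylation means, recombination events, expression means,
#' miRNA patterns). All stochastic emissions in the \code{simulate_*}
#' functions condition on this design, so the design doubles as the ground
#' truth object.
#'
#' @param scenario a [sim_scenario()].
#' @return list with elements \code{scenario}, \code{genes} (gene models in
#'   the [read_gene_annotation()] layout), \code{pairs} (per-pair truth),
#'   \code{sites} (CpG site table), \code{te} (transposon intervals),
#'   \code{mirna} (per-miRNA truth), \code{mirna_loci},
#'   \code{samples}.
#' @export
sim_design <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  sc <- scenario
  n_pairs <- sc$n_pairs

  # --- gene layout (identical coordinates on the two homoeologous chroms)
  pair_chrom <- rep(seq_len(sc$n_chrom_pairs), each = sc$genes_per_chrom)
  idx_on_chrom <- sequence(rep(sc$genes_per_chrom, sc$n_chrom_pairs))
  exon_lens <- matrix(sample(200:700, 3L * n_pairs, replace = TRUE), ncol = 3L)
  intron_lens <- matrix(sample(150:500, 2L * n_pairs, replace = TRUE), ncol = 2L)
  span <- rowSums(exon_lens) + rowSums(intron_lens)
  slot <- max(span) + 4500L
  start <- 2500L + (idx_on_chrom - 1L) * slot
  end <- start + span - 1L
  strand <- sample(c("+", "-"), n_pairs, replace = TRUE)

  mk_genes <- function(sub) {
    chrom <- sprintf("%s%02d", sub, pair_chrom)
    gene_id <- sprintf("g%s%02d_%03d", sub, pair_chrom, idx_on_chrom)
    exons <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      s1 <- start[i]
      e1 <- s1 + exon_lens[i, 1L] - 1L
      s2 <- e1 + intron_lens[i, 1L] + 1L
      e2 <- s2 + exon_lens[i, 2L] - 1L
      s3 <- e2 + intron_lens[i, 2L] + 1L
      e3 <- s3 + exon_lens[i, 3L] - 1L
      ex <- cbind(start = c(s1, s2, s3), end = c(e1, e2, e3))
      if (strand[i] == "-") ex <- ex[3:1, , drop = FALSE]
      exons[[i]] <- ex
    }
    data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
               tss = ifelse(strand == "-", end, start),
               tts = ifelse(strand == "-", start, end),
               start = start, end = end, subgenome = sub,
               exons = I(exons), stringsAsFactors = FALSE)
  }
  genes_R <- mk_genes("R")
  genes_C <- mk_genes("C")
  genes <- rbind(genes_R, genes_C)

  # --- methylation truth
  d_target <- pmin(0.96, pmax(0, .draw_divergence(sc, n_pairs)))
  sign <- sample(c(-1, 1), n_pairs, replace = TRUE)
  centre <- stats::runif(n_pairs, 0.02 + d_target / 2, 0.98 - d_target / 2)
  p_R <- centre + sign * d_target / 2
  p_C <- centre - sign * d_target / 2
  if (!is.null(sc$constant_methylation)) {
    p_R <- rep(sc$constant_methylation, n_pairs)
    p_C <- rep(sc$constant_methylation, n_pairs)
  }

  recombined <- rep(FALSE, n_pairs)
  if (sc$n_recombined_genes > 0L) {
    recombined[sample.int(n_pairs, sc$n_recombined_genes)] <- TRUE
  }
  donor <- rep(NA_character_, n_pairs)
  donor[recombined] <- sample(c("R", "C"), sum(recombined), replace = TRUE)

  # triploid promoter means: the acceptor homoeolog carries the donor's
  # promoter, in both triploids (event inherited from the 4n ancestor)
  tri_p_R <- ifelse(recombined & donor == "C", p_C, p_R)
  tri_p_C <- ifelse(recombined & donor == "R", p_R, p_C)

  # resequencing copy numbers after the exchange (one copy moved to donor)
  shift <- ifelse(!recombined, 0L, ifelse(donor == "C", -1L, +1L))
  copy_post <- function(genotype) {
    cn <- genotype_copy_numbers(genotype)
    data.frame(copy_R = pmax(0L, cn[["R"]] + shift),
               copy_C = pmax(0L, cn[["C"]] - shift))
  }

  # --- expression truth (per-two-copy parental means)
  mu_R <- stats::rlnorm(n_pairs, log(sc$mean_expression), sc$expression_sdlog)
  mu_C <- mu_R * 2^stats::rnorm(n_pairs, 0, 0.25)

  pairs <- data.frame(
    pair_id = sprintf("pair%04d", seq_len(n_pairs)),
    gene_R = genes_R$gene_id, gene_C = genes_C$gene_id,
    chrom_R = genes_R$chrom, chrom_C = genes_C$chrom,
    length = span,
    p_R = p_R, p_C = p_C, d_parent = p_R - p_C,
    tri_p_R = tri_p_R, tri_p_C = tri_p_C,
    d_triploid = tri_p_R - tri_p_C,
    recombined = recombined, donor = donor,
    mu_R = mu_R, mu_C = mu_C,
    stringsAsFactors = FALSE)
  cp1 <- copy_post("3nR2C")
  cp2 <- copy_post("3nRC2")
  pairs$copy_R_3nR2C <- cp1$copy_R
  pairs$copy_C_3nR2C <- cp1$copy_C
  pairs$copy_R_3nRC2 <- cp2$copy_R
  pairs$copy_C_3nRC2 <- cp2$copy_C
  pairs$true_class_3nR2C <- classify_dmg(pairs$d_parent, pairs$d_triploid)
  pairs$true_class_3nRC2 <- pairs$true_class_3nR2C

  # --- CpG sites (promoter + body per gene, identical layout R/C)
  mk_sites <- function(g, pair_idx, part, n_sites, mean_parent, mean_tri) {
    if (n_sites == 0L) return(NULL)
    minus <- g$strand == "-"
    rng <- switch(part,
      promoter = if (minus) c(g$tss + 1L, g$tss + 2000L)
                 else c(g$tss - 2000L, g$tss - 1L),
      downstream = if (minus) c(g$tts - 2000L, g$tts - 1L)
                   else c(g$tts + 1L, g$tts + 2000L),
      c(g$start, g$end))
    pos <- sort(sample(rng[1L]:rng[2L], n_sites))
    data.frame(chrom = g$chrom, pos = pos, strand = "+", context = "CpG",
               gene = g$gene_id, pair = pair_idx, part = part,
               subgenome = g$subgenome,
               mean_parent = mean_parent, mean_tri = mean_tri,
               stringsAsFactors = FALSE)
  }
  body_m <- if (!is.null(sc$constant_methylation)) sc$constant_methylation
            else sc$body_methylation
  site_list <- vector("list", 6L * n_pairs)
  k <- 0L
  for (i in seq_len(n_pairs)) {
    k <- k + 1L
    site_list[[k]] <- mk_sites(genes_R[i, ], i, "promoter",
                               sc$cpgs_per_promoter, p_R[i], tri_p_R[i])
    k <- k + 1L
    site_list[[k]] <- mk_sites(genes_R[i, ], i, "body",
                               sc$cpgs_per_body, body_m, body_m)
    k <- k + 1L
    site_list[[k]] <- mk_sites(genes_R[i, ], i, "downstream",
                               sc$cpgs_per_body, body_m, body_m)
    k <- k + 1L
    site_list[[k]] <- mk_sites(genes_C[i, ], i, "promoter",
                               sc$cpgs_per_promoter, p_C[i], tri_p_C[i])
    k <- k + 1L
    site_list[[k]] <- mk_sites(genes_C[i, ], i, "body",
                               sc$cpgs_per_body, body_m, body_m)
    k <- k + 1L
    site_list[[k]] <- mk_sites(genes_C[i, ], i, "downstream",
                               sc$cpgs_per_body, body_m, body_m)
  }
  sites <- do.call(rbind, site_list)

  # --- transposons: intergenic intervals with their own CpG sites
  te_m <- if (!is.null(sc$constant_methylation)) sc$constant_methylation
          else sc$te_methylation_level
  te_list <- list()
  te_sites <- list()
  chrom_end <- 2500L + sc$genes_per_chrom * slot
  for (sub in c("R", "C")) {
    for (ch in seq_len(sc$n_chrom_pairs)) {
      chrom <- sprintf("%s%02d", sub, ch)
      for (t in seq_len(sc$n_te_per_chrom)) {
        s <- chrom_end + 2500L + (t - 1L) * 5000L
        e <- s + 799L
        te_list[[length(te_list) + 1L]] <-
          data.frame(chrom = chrom, start = s, end = e, strand = "+",
                     stringsAsFactors = FALSE)
        pos <- sort(sample(s:e, 8L))
        te_sites[[length(te_sites) + 1L]] <-
          data.frame(chrom = chrom, pos = pos, strand = "+",
                     context = "CpG", gene = NA_character_, pair = NA_integer_,
                     part = "te", subgenome = sub,
                     mean_parent = te_m, mean_tri = te_m,
                     stringsAsFactors = FALSE)
      }
    }
  }
  te <- do.call(rbind, te_list)
  sites <- rbind(sites, do.call(rbind, te_sites))

  # --- miRNA truth
  counts <- sc$mirna_pattern_counts
  n_mirna <- sum(counts)
  mirna <- NULL
  mirna_loci <- NULL
  if (n_mirna > 0L) {
    pat <- rep(names(counts), counts)
    nrc <- list(P1 = c(2L, 2L), P2 = c(1L, 2L), P3 = c(2L, 1L),
                P4 = c(1L, 1L), P5R = c(2L, 0L), P5C = c(0L, 2L),
                P6R = c(1L, 0L), P6C = c(0L, 1L))
    mirna <- data.frame(
      mirna_id = sprintf("mir%04d", seq_len(n_mirna)),
      pattern = pat,
      n_R = vapply(pat, function(p) nrc[[p]][1L], integer(1)),
      n_C = vapply(pat, function(p) nrc[[p]][2L], integer(1)),
      mu = stats::rlnorm(n_mirna, log(sc$mirna_mean_expression), 0.8),
      row.names = NULL, stringsAsFactors = FALSE)
    loci <- list()
    for (i in seq_len(n_mirna)) {
      for (sub in c("R", "C")) {
        n_loc <- if (sub == "R") mirna$n_R[i] else mirna$n_C[i]
        if (n_loc == 0L) next
        ch <- sample.int(sc$n_chrom_pairs, n_loc, replace = TRUE)
        st <- chrom_end + 40000L + sample.int(50000L, n_loc)
        loci[[length(loci) + 1L]] <- data.frame(
          mirna_id = mirna$mirna_id[i], subgenome = sub,
          chrom = sprintf("%s%02d", sub, ch), start = st, end = st + 21L,
          strand = sample(c("+", "-"), n_loc, replace = TRUE),
          mu = mirna$mu[i], stringsAsFactors = FALSE)
      }
    }
    mirna_loci <- do.call(rbind, loci)
    mirna_loci$locus_id <- paste0(mirna_loci$mirna_id, "@",
                                  mirna_loci$chrom, ":", mirna_loci$start)
    mirna$sequence <- vapply(seq_len(n_mirna), function(i)
      paste(sample(c("A", "C", "G", "U"), 21L, replace = TRUE),
            collapse = ""), character(1))
  }

  samples <- expand.grid(replicate = seq_len(sc$n_replicates),
                         genotype = GENOTYPES, stringsAsFactors = FALSE)
  samples <- samples[c("genotype", "replicate")]
  samples$sample <- paste0(samples$genotype, "_", samples$replicate)

  list(scenario = sc, genes = genes, pairs = pairs, sites = sites, te = te,
       mirna = mirna, mirna_loci = mirna_loci, samples = samples)
}

# which subgenomes a genotype carries
.subgenomes_of <- function(genotype) {
  cn <- genotype_copy_numbers(genotype)
  names(cn)[cn > 0L]
}

#' Simulate per-sample cytosine reports
#'
#' Per site and sample, coverage is Poisson(\code{mean_coverage}); the
#' methylated count is beta-binomial around the genotype's planted mean
#' with precision \code{beta_binomial_precision}. Parents carry only their
#' own subgenome plus the lambda spike-in contig; triploids carry both.
#' Spike-in counts are binomial at \code{error_rate_lambda} (true
#' methylation zero).
#'
#' @param design from [sim_design()].
#' @return named list (sample -> cytosine-record data.frame).
#' @export
simulate_methylation <- function(design) {
  sc <- design$scenario
  set.seed(sc$seed + 1L)
  prec <- sc$beta_binomial_precision
  lam_pos <- seq(100L, by = 37L, length.out = sc$n_lambda_sites)
  lam_ctx <- rep_len(c("CpG", "CHG", "CHH"), sc$n_lambda_sites)
  out <- vector("list", nrow(design$samples))
  names(out) <- design$samples$sample
  for (s in seq_len(nrow(design$samples))) {
    genotype <- design$samples$genotype[s]
    subs <- .subgenomes_of(genotype)
    sel <- design$sites$subgenome %in% subs
    st <- design$sites[sel, , drop = FALSE]
    mean_col <- if (genotype %in% c("3nR2C", "3nRC2")) st$mean_tri
                else st$mean_parent
    n <- nrow(st)
    cov <- stats::rpois(n, sc$mean_coverage)
    m <- pmin(pmax(mean_col, 1e-3), 1 - 1e-3)
    p <- stats::rbeta(n, m * prec, (1 - m) * prec)
    n_meth <- stats::rbinom(n, cov, p)
    rec <- data.frame(chrom = st$chrom, pos = st$pos, strand = st$strand,
                      context = st$context, n_meth = n_meth,
                      n_unmeth = cov - n_meth, stringsAsFactors = FALSE)
    lcov <- stats::rpois(sc$n_lambda_sites, sc$mean_coverage)
    lmeth <- stats::rbinom(sc$n_lambda_sites, lcov, sc$error_rate_lambda)
    lam <- data.frame(chrom = "lambda", pos = lam_pos, strand = "+",
                      context = lam_ctx, n_meth = lmeth,
                      n_unmeth = lcov - lmeth, stringsAsFactors = FALSE)
    rec <- rbind(rec, lam)
    rec <- rec[order(rec$chrom, rec$pos), ]
    rownames(rec) <- NULL
    out[[s]] <- rec
  }
  out
}

# dosage-model mean for one subgenome of a triploid
.triploid_mean <- function(mu, copies, mode, alpha) {
  uncomp <- copies / 2 * mu
  comp <- if (copies > 0L) mu / 2 else rep(0, length(mu))
  switch(mode,
         uncompensated = uncomp,
         compensated = comp,
         partial = alpha * comp + (1 - alpha) * uncomp)
}

#' Simulate the gene-by-sample expression count table
#'
#' Parents express their own subgenome's genes at the per-two-copy mean;
#' triploid subgenome means follow the scenario's dosage model (see
#' [sim_scenario()]). Counts are negative binomial with the scenario
#' dispersion. Genes of an absent subgenome get zero counts.
#'
#' @param design from [sim_design()].
#' @return integer matrix (genes x samples) with sample metadata attached.
#' @export
simulate_expression <- function(design) {
  sc <- design$scenario
  set.seed(sc$seed + 2L)
  pr <- design$pairs
  n <- nrow(pr)
  size <- 1 / sc$nb_dispersion
  gene_ids <- c(pr$gene_R, pr$gene_C)
  mat <- matrix(0L, length(gene_ids), nrow(design$samples),
                dimnames = list(gene_ids, design$samples$sample))
  for (s in seq_len(nrow(design$samples))) {
    genotype <- design$samples$genotype[s]
    mean_R <- switch(genotype,
      "2nRR" = pr$mu_R,
      "2nCC" = rep(0, n),
      .triploid_mean(pr$mu_R, genotype_copy_numbers(genotype)[["R"]],
                     sc$compensation_mode, sc$alpha))
    mean_C <- switch(genotype,
      "2nRR" = rep(0, n),
      "2nCC" = pr$mu_C,
      .triploid_mean(pr$mu_C, genotype_copy_numbers(genotype)[["C"]],
                     sc$compensation_mode, sc$alpha))
    mu <- c(mean_R, mean_C)
    y <- integer(length(mu))
    pos <- mu > 0
    y[pos] <- stats::rnbinom(sum(pos), size = size, mu = mu[pos])
    mat[, s] <- y
  }
  attr(mat, "metadata") <- design$samples
  mat
}

#' Simulate per-gene resequencing read counts for the triploids
#'
#' Reads per gene are Poisson(copy_number x depth_per_copy x length_kb),
#' using the post-recombination copy numbers from the design.
#'
#' @param design from [sim_design()].
#' @return named list (\code{3nR2C}, \code{3nRC2}) of data.frames with
#'   \code{pair_id}, \code{gene_R}, \code{gene_C}, \code{reads_R},
#'   \code{reads_C}, \code{len_R}, \code{len_C}.
#' @export
simulate_reseq <- function(design) {
  sc <- design$scenario
  set.seed(sc$seed + 3L)
  pr <- design$pairs
  out <- list()
  for (genotype in c("3nR2C", "3nRC2")) {
    cR <- pr[[paste0("copy_R_", genotype)]]
    cC <- pr[[paste0("copy_C_", genotype)]]
    kb <- pr$length / 1000
    out[[genotype]] <- data.frame(
      pair_id = pr$pair_id, gene_R = pr$gene_R, gene_C = pr$gene_C,
      reads_R = stats::rpois(nrow(pr), cR * sc$depth_per_copy * kb),
      reads_C = stats::rpois(nrow(pr), cC * sc$depth_per_copy * kb),
      len_R = pr$length, len_C = pr$length,
      stringsAsFactors = FALSE)
  }
  out
}

#' Simulate reciprocal hit tables encoding the true orthology
#'
#' True pairs get mutual top hits passing the reciprocal-best-hit filters
#' (high bitscore, e-value 1e-180, coverage ~0.9); roughly ten percent of
#' genes also get a lower-scoring decoy hit against a random wrong partner.
#' Sequence content is never simulated: the catalogue consumes hit tables.
#'
#' @param design from [sim_design()].
#' @return list with \code{hits_RtoC}, \code{hits_CtoR} (12-column
#'   data.frames in tabular hit layout) and \code{lengths} (gene_id,
#'   length).
#' @export
simulate_hits <- function(design) {
  sc <- design$scenario
  set.seed(sc$seed + 4L)
  pr <- design$pairs
  n <- nrow(pr)
  mk_row <- function(q, s, qlen, frac, score) {
    aln <- pmax(300L, as.integer(round(frac * qlen)))
    data.frame(V1 = q, V2 = s, V3 = round(stats::runif(length(q), 88, 98), 2),
               V4 = aln, V5 = 5L, V6 = 1L, V7 = 1L, V8 = aln, V9 = 1L,
               V10 = aln, V11 = 1e-180, V12 = round(score, 1),
               stringsAsFactors = FALSE)
  }
  true_score <- 0.9 * pr$length + stats::runif(n, 0, 20)
  rc <- mk_row(pr$gene_R, pr$gene_C, pr$length, 0.9, true_score)
  cr <- mk_row(pr$gene_C, pr$gene_R, pr$length, 0.9, true_score)
  decoy_n <- max(0L, round(0.1 * n))
  if (decoy_n > 0L && n >= 2L) {
    qi <- sample.int(n, decoy_n)
    si <- vapply(qi, function(i) sample(setdiff(seq_len(n), i), 1L),
                 integer(1))
    rc <- rbind(rc, mk_row(pr$gene_R[qi], pr$gene_C[si], pr$length[qi],
                           0.85, 0.5 * true_score[qi]))
    cr <- rbind(cr, mk_row(pr$gene_C[qi], pr$gene_R[si], pr$length[qi],
                           0.85, 0.5 * true_score[qi]))
  }
  lengths <- data.frame(gene_id = c(pr$gene_R, pr$gene_C),
                        length = c(pr$length, pr$length),
                        stringsAsFactors = FALSE)
  list(hits_RtoC = rc, hits_CtoR = cr, lengths = lengths)
}

#' Simulate the miRNA locus-by-sample count table
#'
#' Per-locus counts are negative binomial around the miRNA's mean; parents
#' only express loci of their own subgenome.
#'
#' @param design from [sim_design()].
#' @return list with \code{loci} (locus table incl. \code{locus_id}),
#'   \code{counts} (locus x sample matrix), \code{sequences} (named mature
#'   sequences).
#' @export
simulate_mirna <- function(design) {
  sc <- design$scenario
  set.seed(sc$seed + 5L)
  loci <- design$mirna_loci
  if (is.null(loci)) return(NULL)
  size <- 1 / sc$nb_dispersion
  mat <- matrix(0L, nrow(loci), nrow(design$samples),
                dimnames = list(loci$locus_id, design$samples$sample))
  for (s in seq_len(nrow(design$samples))) {
    subs <- .subgenomes_of(design$samples$genotype[s])
    sel <- loci$subgenome %in% subs
    mat[sel, s] <- stats::rnbinom(sum(sel), size = size, mu = loci$mu[sel])
  }
  attr(mat, "metadata") <- design$samples
  seqs <- stats::setNames(design$mirna$sequence, design$mirna$mirna_id)
  list(loci = loci, counts = mat, sequences = seqs)
}

.write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, g$start, g$end, g$strand, g$gene_id))
    ex <- g$exons[[1L]]
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                g$chrom, ex[j, 1L], ex[j, 2L], g$strand,
                                g$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate the full in-silico allotriploid complex and write all files
#'
#' Emits, under \code{outdir}: per-sample cytosine reports
#' (\code{meth_<sample>.tsv}), the gene annotation (\code{genes.gff3}),
#' transposon intervals (\code{te.bed}), reciprocal hit tables and gene
#' lengths, the gene and miRNA-locus count tables, per-triploid
#' resequencing counts, the miRNA locus table and mature sequences, and the
#' ground-truth tables (\code{ground_truth_genes.tsv},
#' \code{ground_truth_mirna.tsv}). Byte-identical across runs with the same
#' scenario.
#'
#' @param scenario a [sim_scenario()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) list with \code{files} (named paths), \code{design}
#'   and \code{truth} (the pair and miRNA truth tables).
#' @export
simulate_complex <- function(scenario, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  design <- sim_design(scenario)
  files <- list()

  files$genes <- file.path(outdir, "genes.gff3")
  .write_gff3(design$genes, files$genes)

  meth <- simulate_methylation(design)
  for (s in names(meth)) {
    f <- file.path(outdir, paste0("meth_", s, ".tsv"))
    write_cytosine_report(meth[[s]], f)
    files[[paste0("meth_", s)]] <- f
  }

  files$te <- file.path(outdir, "te.bed")
  writeLines(sprintf("%s\t%d\t%d\tte%d\t0\t%s", design$te$chrom,
                     design$te$start - 1L, design$te$end,
                     seq_len(nrow(design$te)), design$te$strand), files$te)

  expr <- simulate_expression(design)
  files$counts_genes <- file.path(outdir, "counts_genes.tsv")
  write_count_table(expr, files$counts_genes, id_col = "gene_id")

  reseq <- simulate_reseq(design)
  for (g in names(reseq)) {
    f <- file.path(outdir, paste0("reseq_", g, ".tsv"))
    utils::write.table(reseq[[g]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[paste0("reseq_", g)]] <- f
  }

  hits <- simulate_hits(design)
  files$hits_RtoC <- file.path(outdir, "hits_RtoC.tsv")
  files$hits_CtoR <- file.path(outdir, "hits_CtoR.tsv")
  files$lengths <- file.path(outdir, "gene_lengths.tsv")
  utils::write.table(hits$hits_RtoC, files$hits_RtoC, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(hits$hits_CtoR, files$hits_CtoR, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(hits$lengths, files$lengths, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  mirna <- simulate_mirna(design)
  if (!is.null(mirna)) {
    files$mirna_loci <- file.path(outdir, "mirna_loci.tsv")
    utils::write.table(mirna$loci[c("mirna_id", "subgenome", "chrom",
                                    "start", "end", "strand", "locus_id")],
                       files$mirna_loci, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files$counts_mirna <- file.path(outdir, "counts_mirna_loci.tsv")
    write_count_table(mirna$counts, files$counts_mirna, id_col = "locus_id")
    files$mirna_fasta <- file.path(outdir, "mirna_mature.fa")
    write_fasta(mirna$sequences, files$mirna_fasta)
  }

  files$truth_genes <- file.path(outdir, "ground_truth_genes.tsv")
  utils::write.table(design$pairs, files$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(design$mirna)) {
    files$truth_mirna <- file.path(outdir, "ground_truth_mirna.tsv")
    utils::write.table(design$mirna[c("mirna_id", "pattern", "n_R", "n_C")],
                       files$truth_mirna, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  invisible(list(files = files, design = design,
                 truth = list(genes = design$pairs, mirna = design$mirna)))
}
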