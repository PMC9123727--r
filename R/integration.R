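# Integration: DE-DM correlation quadrants and the end-to-end pipeline
# runner. Orientation convention throughout: every difference is
# first-named group minus second-named group of the comparison.

#' Join differential expression and differential methylation into quadrants
#'
#' Genes present in both inputs are placed in the \emph{negative} quadrant
#' when the signs of the DE value (log2 fold change) and the DM value
#' (promoter methylation difference, same comparison orientation) are
#' opposite, and in the \emph{positive} quadrant when they agree. Genes
#' with a zero or undefined value on either axis are excluded and counted.
#' A gene is \emph{significant} when its DE call passed ([call_de()]'s
#' \code{is_de}) and |DM| reaches \code{dm_threshold}.
#'
#' @param de data.frame from [call_de()] (\code{feature}, \code{log2fc},
#'   \code{is_de}).
#' @param dm named numeric vector gene -> methylation difference, oriented
#'   as the DE comparison.
#' @param dm_threshold minimum |DM| for significance, default 0.1.
#' @return list with \code{records} (gene, de_value, dm_value, quadrant,
#'   significant) and \code{counts} (negative, positive,
#'   significant_negative, significant_positive, excluded, total).
#' @export
de_dm_quadrants <- function(de, dm, dm_threshold = 0.1) {
  common <- intersect(de$feature, names(dm))
  de_v <- stats::setNames(de$log2fc, de$feature)[common]
  is_de <- stats::setNames(de$is_de, de$feature)[common]
  dm_v <- dm[common]
  ok <- is.finite(de_v) & is.finite(dm_v) & de_v != 0 & dm_v != 0
  records <- data.frame(
    gene = common[ok],
    de_value = unname(de_v[ok]),
    dm_value = unname(dm_v[ok]),
    quadrant = ifelse(sign(de_v[ok]) * sign(dm_v[ok]) < 0,
                      "negative", "positive"),
    significant = unname(is_de[ok]) & abs(dm_v[ok]) >= dm_threshold,
    stringsAsFactors = FALSE)
  counts <- c(
    negative = sum(records$quadrant == "negative"),
    positive = sum(records$quadrant == "positive"),
    significant_negative = sum(records$significant &
                                 records$quadrant == "negative"),
    significant_positive = sum(records$significant &
                                 records$quadrant == "positive"),
    excluded = sum(!ok),
    total = length(common))
  list(records = records, counts = counts)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full subgenome-resolved pipeline on a simulated complex
#'
#' Simulates an allotriploid complex from \code{scenario}, reads every
#' emitted file back through the package's parsers, and runs the stages in
#' order: homoeolog catalogue, methylation (spike-in error rates, promoter
#' levels, element profiles, triploid-vs-triploid DMRs), promoter
#' divergence / DMG / HRG prediction, read-ratio recombination calls,
#' expression DE and the dosage scaling matrix, miRNA patterns /
#' aggregation / DE, and the DE-DM quadrant join. One tidy TSV per stage
#' plus a JSON summary and a run log are written under \code{outdir}.
#'
#' @param scenario a [sim_scenario()]; its seed makes the whole run
#'   deterministic.
#' @param outdir report directory (created).
#' @return (invisibly) list with \code{summary} and the per-stage output
#'   paths.
#' @export
run_pipeline <- function(scenario = sim_scenario(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  simdir <- file.path(outdir, "sim")
  sim <- .stage("simulate", simulate_complex(scenario, simdir))
  f <- sim$files
  paths <- list()

  genes <- .stage("annotation", read_gene_annotation(f$genes, "gff3"))
  samples <- sim$design$samples

  # --- catalogue
  cat_out <- .stage("catalog", {
    rc <- read_hit_table(f$hits_RtoC, f$lengths)
    cr <- read_hit_table(f$hits_CtoR, f$lengths)
    rbh <- reciprocal_best_hits(rc, cr)
    rbh <- add_pair_chromosomes(rbh, genes)
    ocp <- assign_orthologous_chromosomes(rbh)
    build_catalog(rbh, ocp)
  })
  paths$catalog <- .write_tsv(cat_out, file.path(outdir, "catalog.tsv"))

  # --- methylation
  meth <- .stage("methylation", {
    recs <- lapply(samples$sample, function(s)
      read_cytosine_report(f[[paste0("meth_", s)]]))
    names(recs) <- samples$sample
    err <- vapply(recs, function(r)
      estimate_error_rate(r[r$chrom == "lambda", ]), numeric(1))
    pooled <- lapply(GENOTYPES, function(g)
      pool_replicates(recs[samples$sample[samples$genotype == g]]))
    names(pooled) <- GENOTYPES
    prom <- lapply(pooled, function(p) promoter_levels(p, genes))
    prof <- do.call(rbind, lapply(GENOTYPES, function(g) {
      pr <- binned_profile(pooled[[g]], genes)
      pr$genotype <- g
      pr
    }))
    te_iv <- read_bed_intervals(f$te)
    te_prof <- do.call(rbind, lapply(GENOTYPES, function(g) {
      pr <- te_methylation(pooled[[g]], te_iv)
      pr$genotype <- g
      pr
    }))
    dmrs <- call_dmrs(recs[samples$sample[samples$genotype == "3nR2C"]],
                      recs[samples$sample[samples$genotype == "3nRC2"]])
    list(records = recs, error = err, pooled = pooled, prom = prom,
         prof = prof, te_prof = te_prof, dmrs = dmrs)
  })
  paths$error_rates <- .write_tsv(
    data.frame(sample = names(meth$error), error_rate = meth$error),
    file.path(outdir, "error_rates.tsv"))
  paths$profiles <- .write_tsv(meth$prof, file.path(outdir, "profiles.tsv"))
  paths$te_profiles <- .write_tsv(meth$te_prof,
                                  file.path(outdir, "te_profiles.tsv"))
  paths$dmrs <- .write_tsv(meth$dmrs, file.path(outdir, "dmrs.tsv"))
  prom_tab <- do.call(rbind, lapply(GENOTYPES, function(g)
    data.frame(genotype = g, gene_id = names(meth$prom[[g]]),
               level = unname(meth$prom[[g]]), stringsAsFactors = FALSE)))
  paths$promoters <- .write_tsv(prom_tab, file.path(outdir, "promoters.tsv"))

  # --- DMG / HRG
  dmg <- .stage("dmg_hrg", {
    div <- compute_divergence(cat_out, meth$prom)
    predict_hrgs(div)
  })
  paths$dmg <- .write_tsv(dmg, file.path(outdir, "dmg.tsv"))

  # --- read-ratio recombination
  hr <- .stage("hr_readratio", {
    lapply(c("3nR2C", "3nRC2"), function(g) {
      rs <- utils::read.table(f[[paste0("reseq_", g)]], sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
      rs <- rs[rs$gene_R %in% cat_out$gene_R, ]
      call_hr(rs, genotype = g)
    })
  })
  names(hr) <- c("3nR2C", "3nRC2")
  paths$hr_3nR2C <- .write_tsv(hr[["3nR2C"]],
                               file.path(outdir, "hr_3nR2C.tsv"))
  paths$hr_3nRC2 <- .write_tsv(hr[["3nRC2"]],
                               file.path(outdir, "hr_3nRC2.tsv"))

  # --- expression: DE per subgenome comparison + dosage matrix
  expr <- .stage("expression", {
    counts <- read_count_table(f$counts_genes)
    md <- attr(counts, "metadata")
    cols <- function(g) md$sample[md$genotype == g]
    sub_genes <- list(R = cat_out$gene_R, C = cat_out$gene_C)
    comparisons <- list(
      c("3nR2C", "2nRR", "R"), c("3nRC2", "2nRR", "R"),
      c("3nR2C", "2nCC", "C"), c("3nRC2", "2nCC", "C"),
      c("3nR2C", "3nRC2", "R"), c("3nR2C", "3nRC2", "C"))
    de <- lapply(comparisons, function(cmp) {
      sub <- counts[sub_genes[[cmp[3L]]], c(cols(cmp[1L]), cols(cmp[2L]))]
      sub <- filter_low_counts(sub)
      res <- call_de(sub, cols(cmp[1L]), cols(cmp[2L]))
      res$comparison <- paste0(cmp[1L], "_vs_", cmp[2L])
      res$subgenome <- cmp[3L]
      res
    })
    names(de) <- vapply(comparisons, function(cmp)
      paste0(cmp[1L], "_vs_", cmp[2L], "_", cmp[3L]), character(1))
    # dosage: whole-library CPM (normalising within the tested subgenome
    # would cancel the dosage shift itself)
    cpm0 <- cpm(counts, rep(1, ncol(counts)))
    dose <- list()
    for (tri in c("3nR2C", "3nRC2")) {
      for (sub in c("R", "C")) {
        parent <- if (sub == "R") "2nRR" else "2nCC"
        g <- sub_genes[[sub]]
        x <- rowMeans(cpm0[g, cols(tri), drop = FALSE])
        y <- rowMeans(cpm0[g, cols(parent), drop = FALSE])
        keep <- x + y > 0
        d <- dosage_scaling_test(x[keep], y[keep])
        d$triploid <- tri
        d$subgenome <- sub
        d$parent <- parent
        dose[[paste(tri, sub)]] <- d
      }
    }
    list(counts = counts, de = de, dosage = do.call(rbind, dose))
  })
  paths$de <- .write_tsv(do.call(rbind, expr$de), file.path(outdir, "de.tsv"))
  paths$dosage <- .write_tsv(expr$dosage, file.path(outdir, "dosage.tsv"))

  # --- miRNA
  mir <- .stage("mirna", {
    loci <- read_mirna_loci(f$mirna_loci)
    loci_full <- utils::read.table(f$mirna_loci, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
    pat <- assign_patterns(loci)
    lc <- read_count_table(f$counts_mirna)
    agg <- aggregate_expression(lc, stats::setNames(loci_full$mirna_id,
                                                    loci_full$locus_id))
    md <- attr(lc, "metadata")
    cols <- function(g) md$sample[md$genotype == g]
    de <- de_mirna(agg, cols("3nR2C"), cols("3nRC2"))
    list(patterns = pat, agg = agg, de = de)
  })
  paths$mirna_patterns <- .write_tsv(mir$patterns,
                                     file.path(outdir, "mirna_patterns.tsv"))
  paths$mirna_de <- .write_tsv(mir$de, file.path(outdir, "mirna_de.tsv"))

  # --- integration: DE vs promoter DM quadrants per triploid-parent pair
  dedm <- .stage("integration", {
    out <- list()
    for (cmp in list(c("3nR2C", "2nRR", "R"), c("3nRC2", "2nRR", "R"),
                     c("3nR2C", "2nCC", "C"), c("3nRC2", "2nCC", "C"))) {
      key <- paste0(cmp[1L], "_vs_", cmp[2L], "_", cmp[3L])
      de <- expr$de[[key]]
      gset <- if (cmp[3L] == "R") cat_out$gene_R else cat_out$gene_C
      dm <- meth$prom[[cmp[1L]]][gset] - meth$prom[[cmp[2L]]][gset]
      q <- de_dm_quadrants(de, dm)
      q$records$comparison <- key
      out[[key]] <- q
    }
    out
  })
  dedm_records <- do.call(rbind, lapply(dedm, function(q) q$records))
  paths$dedm <- .write_tsv(dedm_records, file.path(outdir, "dedm.tsv"))

  # --- summary + log
  summary <- list(
    n_pairs_catalog = nrow(cat_out),
    n_pairs_divergence = nrow(dmg),
    dmg_counts = as.list(table(dmg$dmg_class)),
    n_hrg = sum(dmg$is_hrg),
    hr_flagged = vapply(hr, function(h) sum(h$flagged), integer(1)),
    hr_one_sided = vapply(hr, function(h) sum(h$one_sided), integer(1)),
    dmr_count = nrow(meth$dmrs),
    error_rates = as.list(meth$error),
    dosage_verdicts = stats::setNames(
      as.list(expr$dosage$verdict),
      paste(expr$dosage$triploid, expr$dosage$subgenome,
            paste0("x", expr$dosage$scale), sep = "_")),
    mirna_pattern_histogram = as.list(table(mir$patterns$pattern)),
    mirna_de_count = sum(mir$de$is_de),
    dedm_counts = lapply(dedm, function(q) as.list(q$counts)))
  paths$summary <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths$log <- file.path(outdir, "run_log.txt")
  writeLines(c(
    paste("R version:", R.version.string),
    paste("package version:",
          as.character(utils::packageVersion("allotriploid"))),
    paste("seed:", scenario$seed),
    paste("scenario:", paste(utils::capture.output(print(scenario)),
                             collapse = " | ")),
    paste("date:", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))),
    paths$log)

  invisible(list(summary = summary, paths = paths, scenario = scenario))
}
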