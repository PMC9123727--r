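# Methylation calling and summarisation: binomial site test against the
# lambda spike-in error rate, region/binned element levels, window DMRs.

#' Estimate the bisulfite non-conversion error rate from the lambda spike-in
#'
#' The spike-in is unmethylated phage DNA, so any methylated call on it is a
#' conversion failure (or sequencing error). The estimate is the pooled
#' ratio sum(n_meth) / sum(coverage) over all contexts.
#'
#' @param lambda_records cytosine records restricted to the spike-in contig.
#' @return the estimated error rate; a warning is emitted when it is >= 0.05,
#'   which indicates a failed conversion.
#' @export
estimate_error_rate <- function(lambda_records) {
  total <- sum(lambda_records$n_meth) + sum(lambda_records$n_unmeth)
  if (total == 0L) stop("zero total coverage on the spike-in contig")
  rate <- sum(lambda_records$n_meth) / total
  if (rate >= 0.05) {
    warning(sprintf("spike-in error rate %.3f >= 0.05: bisulfite conversion looks unreliable", rate))
  }
  rate
}

#' Call methylated cytosines with a one-sided exact binomial test
#'
#' Per site, the p-value is the upper binomial tail
#' P(X >= n_meth | n = coverage, p0 = error_rate). Benjamini-Hochberg
#' correction is applied across all tested sites of the sample (those with
#' coverage >= \code{min_coverage}); sites below the coverage threshold are
#' never called methylated and get \code{NA} q-values.
#'
#' @param records cytosine records (one sample).
#' @param error_rate non-conversion error rate in (0, 1), typically from
#'   [estimate_error_rate()].
#' @param min_coverage minimum read coverage for a site to be testable;
#'   default 5 (i.e. coverage strictly greater than 4).
#' @param fdr FDR threshold for the methylated call.
#' @return \code{records} with added columns \code{coverage}, \code{level},
#'   \code{p_value}, \code{q_value}, \code{is_methylated}.
#' @export
call_methylation <- function(records, error_rate, min_coverage = 5L,
                             fdr = 0.05) {
  stopifnot(error_rate > 0, error_rate < 1)
  coverage <- records$n_meth + records$n_unmeth
  p <- stats::pbinom(records$n_meth - 1L, coverage, error_rate,
                     lower.tail = FALSE)
  p[coverage == 0L] <- NA_real_
  tested <- coverage >= min_coverage
  q <- rep(NA_real_, length(p))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  records$coverage <- coverage
  records$level <- ifelse(coverage > 0L, records$n_meth / coverage, NA_real_)
  records$p_value <- p
  records$q_value <- q
  records$is_methylated <- tested & !is.na(q) & q < fdr
  records
}

#' Methylation level of a genomic interval
#'
#' Coverage weighting (the default) is the pooled-count ratio
#' sum(n_meth) / sum(coverage) over covered sites in the interval; site
#' weighting is the unweighted mean of per-site levels. The two differ
#' whenever coverage is uneven across sites.
#'
#' @param records cytosine records (counts pooled over replicates upstream
#'   if desired).
#' @param chrom,start,end 1-based inclusive interval.
#' @param weighting \code{"coverage"} or \code{"site"}.
#' @param context restrict to this context (default CpG).
#' @return level in \[0, 1\], or \code{NA} when the interval has no covered
#'   site.
#' @export
region_level <- function(records, chrom, start, end,
                         weighting = c("coverage", "site"),
                         context = "CpG") {
  weighting <- match.arg(weighting)
  stopifnot(end >= start)
  sel <- records$chrom == chrom & records$pos >= start & records$pos <= end &
    records$context == context & (records$n_meth + records$n_unmeth) > 0L
  if (!any(sel)) return(NA_real_)
  m <- records$n_meth[sel]
  u <- records$n_unmeth[sel]
  if (weighting == "coverage") sum(m) / sum(m + u) else mean(m / (m + u))
}

# Region intervals for one gene, in transcript (5'->3') order.
# Each element is a matrix with columns start, end; rows in transcript order.
.gene_regions <- function(gene, flank_bp) {
  ex <- gene$exons[[1L]]
  n <- nrow(ex)
  minus <- gene$strand == "-"
  tss <- gene$tss
  tts <- gene$tts
  up <- if (minus) c(tss + 1L, tss + flank_bp) else c(tss - flank_bp, tss - 1L)
  down <- if (minus) c(tts - flank_bp, tts - 1L) else c(tts + 1L, tts + flank_bp)
  clip <- function(iv) {
    if (iv[1L] < 1L) {
      message("flank truncated at chromosome start for gene ", gene$gene_id)
      iv[1L] <- 1L
    }
    if (iv[2L] < iv[1L]) return(NULL)
    matrix(iv, ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  introns <- NULL
  if (n >= 2L) {
    introns <- matrix(NA_integer_, n - 1L, 2L,
                      dimnames = list(NULL, c("start", "end")))
    for (i in seq_len(n - 1L)) {
      if (minus) {
        introns[i, ] <- c(ex[i + 1L, "end"] + 1L, ex[i, "start"] - 1L)
      } else {
        introns[i, ] <- c(ex[i, "end"] + 1L, ex[i + 1L, "start"] - 1L)
      }
    }
    introns <- introns[introns[, 2L] >= introns[, 1L], , drop = FALSE]
  }
  regions <- list(
    Up2k = clip(up),
    first_exon = ex[1L, , drop = FALSE],
    first_intron = if (!is.null(introns) && nrow(introns) >= 1L)
      introns[1L, , drop = FALSE],
    inner_exon = if (n >= 3L) ex[2:(n - 1L), , drop = FALSE],
    inner_intron = if (!is.null(introns) && nrow(introns) >= 2L)
      introns[2:nrow(introns), , drop = FALSE],
    last_exon = if (n >= 2L) ex[n, , drop = FALSE],
    gene_body = matrix(c(min(tss, tts), max(tss, tts)), ncol = 2L,
                       dimnames = list(NULL, c("start", "end"))),
    Down2k = clip(down)
  )
  regions[!vapply(regions, is.null, logical(1))]
}

# Accumulate methylated/unmethylated counts of sites into n_bins equal-length
# bins along the concatenated transcript-oriented axis of `intervals`.
.bin_counts <- function(pos, n_meth, n_unmeth, intervals, strand, n_bins) {
  lens <- intervals[, "end"] - intervals[, "start"] + 1L
  before <- cumsum(c(0L, lens[-length(lens)]))
  total <- sum(lens)
  acc <- matrix(0, n_bins, 2L, dimnames = list(NULL, c("n_meth", "n_unmeth")))
  for (k in seq_len(nrow(intervals))) {
    sel <- pos >= intervals[k, "start"] & pos <= intervals[k, "end"]
    if (!any(sel)) next
    within <- if (strand == "-") intervals[k, "end"] - pos[sel]
              else pos[sel] - intervals[k, "start"]
    off <- before[k] + within
    bin <- pmin(n_bins, floor(off / total * n_bins) + 1L)
    acc[, 1L] <- acc[, 1L] + as.numeric(tapply(n_meth[sel], factor(bin, levels = seq_len(n_bins)), sum, default = 0))
    acc[, 2L] <- acc[, 2L] + as.numeric(tapply(n_unmeth[sel], factor(bin, levels = seq_len(n_bins)), sum, default = 0))
  }
  acc
}

GENE_REGIONS <- c("Up2k", "first_exon", "first_intron", "inner_exon",
                  "inner_intron", "last_exon", "gene_body", "Down2k")

#' Binned methylation profile over gene elements
#'
#' Each gene element (2 kb upstream flank, first/inner/last exon,
#' first/inner intron, gene body, 2 kb downstream flank) is divided into 20
#' equal-length bins along the transcript orientation, and the profile is
#' the coverage-weighted average over genes: methylated and total read
#' counts are accumulated per region x bin across all genes and the bin
#' level is their ratio. Genes lacking an element (e.g. single-exon genes
#' have no introns) simply contribute nothing to it.
#'
#' @param records cytosine records (pooled counts for the group of
#'   interest).
#' @param genes gene models from [read_gene_annotation()].
#' @param flank_bp flank size, default 2000.
#' @param n_bins bins per region, default 20.
#' @return data.frame with columns \code{region}, \code{bin}, \code{level},
#'   \code{n_meth}, \code{n_unmeth}; regions ordered 5' to 3'.
#' @export
binned_profile <- function(records, genes, flank_bp = 2000L, n_bins = 20L) {
  records <- records[records$context == "CpG" &
                       (records$n_meth + records$n_unmeth) > 0L, , drop = FALSE]
  by_chrom <- split(records, records$chrom)
  acc <- lapply(GENE_REGIONS, function(r)
    matrix(0, n_bins, 2L, dimnames = list(NULL, c("n_meth", "n_unmeth"))))
  names(acc) <- GENE_REGIONS
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, , drop = FALSE]
    sites <- by_chrom[[gene$chrom]]
    if (is.null(sites)) next
    regions <- .gene_regions(gene, flank_bp)
    for (rn in names(regions)) {
      acc[[rn]] <- acc[[rn]] + .bin_counts(sites$pos, sites$n_meth,
                                           sites$n_unmeth, regions[[rn]],
                                           gene$strand, n_bins)
    }
  }
  out <- do.call(rbind, lapply(GENE_REGIONS, function(rn) {
    data.frame(region = rn, bin = seq_len(n_bins),
               n_meth = acc[[rn]][, 1L], n_unmeth = acc[[rn]][, 2L],
               stringsAsFactors = FALSE)
  }))
  tot <- out$n_meth + out$n_unmeth
  out$level <- ifelse(tot > 0, out$n_meth / tot, NA_real_)
  out$region <- factor(out$region, levels = GENE_REGIONS)
  out[c("region", "bin", "level", "n_meth", "n_unmeth")]
}

TE_REGIONS <- c("TE_flank_up", "TE_body", "TE_flank_down")

#' Binned methylation profile over transposon bodies and flanks
#'
#' As [binned_profile()] but with the three regions upstream 2 kb flank,
#' element body and downstream 2 kb flank. Strand is taken as \code{+} when
#' unknown.
#'
#' @param records cytosine records (pooled counts).
#' @param te_intervals data.frame with \code{chrom}, \code{start},
#'   \code{end} and optionally \code{strand} (1-based inclusive, e.g.
#'   [read_bed_intervals()]).
#' @param flank_bp,n_bins as in [binned_profile()].
#' @export
te_methylation <- function(records, te_intervals, flank_bp = 2000L,
                           n_bins = 20L) {
  records <- records[records$context == "CpG" &
                       (records$n_meth + records$n_unmeth) > 0L, , drop = FALSE]
  by_chrom <- split(records, records$chrom)
  if (is.null(te_intervals$strand)) te_intervals$strand <- "+"
  acc <- lapply(TE_REGIONS, function(r)
    matrix(0, n_bins, 2L, dimnames = list(NULL, c("n_meth", "n_unmeth"))))
  names(acc) <- TE_REGIONS
  iv <- function(a, b) {
    if (a < 1L) a <- 1L
    if (b < a) return(NULL)
    matrix(c(a, b), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  for (i in seq_len(nrow(te_intervals))) {
    te <- te_intervals[i, ]
    sites <- by_chrom[[te$chrom]]
    if (is.null(sites)) next
    minus <- identical(te$strand, "-")
    regions <- list(
      TE_flank_up = if (minus) iv(te$end + 1L, te$end + flank_bp)
                    else iv(te$start - flank_bp, te$start - 1L),
      TE_body = iv(te$start, te$end),
      TE_flank_down = if (minus) iv(te$start - flank_bp, te$start - 1L)
                      else iv(te$end + 1L, te$end + flank_bp)
    )
    for (rn in names(regions)) {
      if (is.null(regions[[rn]])) next
      acc[[rn]] <- acc[[rn]] + .bin_counts(sites$pos, sites$n_meth,
                                           sites$n_unmeth, regions[[rn]],
                                           if (minus) "-" else "+", n_bins)
    }
  }
  out <- do.call(rbind, lapply(TE_REGIONS, function(rn) {
    data.frame(region = rn, bin = seq_len(n_bins),
               n_meth = acc[[rn]][, 1L], n_unmeth = acc[[rn]][, 2L],
               stringsAsFactors = FALSE)
  }))
  tot <- out$n_meth + out$n_unmeth
  out$level <- ifelse(tot > 0, out$n_meth / tot, NA_real_)
  out$region <- factor(out$region, levels = TE_REGIONS)
  out[c("region", "bin", "level", "n_meth", "n_unmeth")]
}

#' Call differentially methylated regions with a pooled-count window test
#'
#' The genome is tiled in non-overlapping windows of \code{window_bp}.
#' Replicate counts are pooled per group within each window and the pooled
#' 2x2 table (methylated/unmethylated by group) is tested with a two-sided
#' Fisher exact test. Benjamini-Hochberg correction runs across all windows
#' with at least \code{min_cpgs} covered CpG sites; windows that are
#' significant at \code{fdr} with |level difference| >= \code{min_delta}
#' are reported, with adjacent significant windows merged.
#'
#' @param group1,group2 lists of cytosine-record data.frames (one per
#'   replicate).
#' @param window_bp window size in bp.
#' @param min_cpgs minimum covered CpG sites (union of both groups) for a
#'   window to be tested.
#' @param min_delta minimum absolute difference of pooled levels.
#' @param fdr BH threshold.
#' @return data.frame of merged DMRs with columns \code{chrom},
#'   \code{start}, \code{end}, \code{mean1}, \code{mean2}, \code{delta},
#'   \code{q_value}.
#' @export
call_dmrs <- function(group1, group2, window_bp = 100L, min_cpgs = 4L,
                      min_delta = 0.1, fdr = 0.05) {
  stopifnot(length(group1) >= 1L, length(group2) >= 1L)
  pool <- function(group) {
    df <- do.call(rbind, lapply(group, function(r) {
      r[r$context == "CpG", c("chrom", "pos", "n_meth", "n_unmeth")]
    }))
    df$win <- (df$pos - 1L) %/% window_bp
    key <- paste0(df$chrom, ":", df$win)
    list(m = rowsum(df$n_meth, key), u = rowsum(df$n_unmeth, key),
         sites = df[df$n_meth + df$n_unmeth > 0L,
                    c("chrom", "pos", "win")])
  }
  p1 <- pool(group1)
  p2 <- pool(group2)
  keys <- union(rownames(p1$m), rownames(p2$m))
  if (!length(keys)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mean1 = numeric(), mean2 = numeric(),
                      delta = numeric(), q_value = numeric()))
  }
  get <- function(p, keys) {
    m <- stats::setNames(rep(0, length(keys)), keys)
    m[rownames(p$m)] <- p$m[, 1L]
    u <- stats::setNames(rep(0, length(keys)), keys)
    u[rownames(p$u)] <- p$u[, 1L]
    list(m = m, u = u)
  }
  g1 <- get(p1, keys)
  g2 <- get(p2, keys)
  sites <- unique(rbind(p1$sites, p2$sites))
  ncpg <- table(paste0(sites$chrom, ":", sites$win))
  n_sites <- stats::setNames(rep(0L, length(keys)), keys)
  n_sites[names(ncpg)] <- as.integer(ncpg)

  testable <- which(n_sites >= min_cpgs)
  pvals <- rep(NA_real_, length(keys))
  for (i in testable) {
    tab <- matrix(c(g1$m[i], g1$u[i], g2$m[i], g2$u[i]), nrow = 2L)
    pvals[i] <- stats::fisher.test(round(tab))$p.value
  }
  qvals <- rep(NA_real_, length(keys))
  qvals[testable] <- stats::p.adjust(pvals[testable], method = "BH")
  t1 <- g1$m + g1$u
  t2 <- g2$m + g2$u
  mean1 <- ifelse(t1 > 0, g1$m / t1, NA_real_)
  mean2 <- ifelse(t2 > 0, g2$m / t2, NA_real_)
  delta <- mean1 - mean2
  sig <- !is.na(qvals) & qvals < fdr & !is.na(delta) & abs(delta) >= min_delta

  if (!any(sig)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mean1 = numeric(), mean2 = numeric(),
                      delta = numeric(), q_value = numeric()))
  }
  chrom <- sub(":[^:]*$", "", keys)
  win <- as.integer(sub("^.*:", "", keys))
  sel <- which(sig)
  sel <- sel[order(chrom[sel], win[sel])]
  runs <- cumsum(c(TRUE, chrom[sel][-1L] != chrom[sel][-length(sel)] |
                     diff(win[sel]) != 1L))
  out <- do.call(rbind, lapply(split(sel, runs), function(idx) {
    data.frame(chrom = chrom[idx][1L],
               start = win[idx][1L] * window_bp + 1L,
               end = (win[idx][length(idx)] + 1L) * window_bp,
               mean1 = sum(g1$m[idx]) / sum(g1$m[idx] + g1$u[idx]),
               mean2 = sum(g2$m[idx]) / sum(g2$m[idx] + g2$u[idx]),
               q_value = min(qvals[idx]),
               stringsAsFactors = FALSE)
  }))
  out$delta <- out$mean1 - out$mean2
  rownames(out) <- NULL
  out[c("chrom", "start", "end", "mean1", "mean2", "delta", "q_value")]
}

#' Promoter methylation levels for a set of genes
#'
#' The promoter is the \code{flank_bp} (default 2 kb) region immediately
#' upstream of the TSS, strand-aware. Levels are computed with
#' [region_level()].
#'
#' @param records cytosine records (pool replicates upstream for a
#'   per-genotype level).
#' @param genes gene models.
#' @param flank_bp promoter size.
#' @param weighting passed to [region_level()].
#' @return named numeric vector, gene_id -> level (\code{NA} when the
#'   promoter has no covered CpG).
#' @export
promoter_levels <- function(records, genes, flank_bp = 2000L,
                            weighting = "coverage") {
  out <- rep(NA_real_, nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    minus <- genes$strand[i] == "-"
    tss <- genes$tss[i]
    start <- if (minus) tss + 1L else max(1L, tss - flank_bp)
    end <- if (minus) tss + flank_bp else tss - 1L
    if (end < start) next
    out[i] <- region_level(records, genes$chrom[i], start, end,
                           weighting = weighting)
  }
  out
}

#' Pool cytosine-record replicates by summing counts per site
#' @param replicates list of cytosine-record data.frames.
#' @return one data.frame with counts summed per (chrom, pos, strand,
#'   context).
#' @export
pool_replicates <- function(replicates) {
  df <- do.call(rbind, replicates)
  key <- paste(df$chrom, df$pos, df$strand, df$context, sep = "\r")
  m <- rowsum(df$n_meth, key)
  u <- rowsum(df$n_unmeth, key)
  first <- !duplicated(key)
  out <- df[first, c("chrom", "pos", "strand", "context")]
  ord <- match(paste(out$chrom, out$pos, out$strand, out$context, sep = "\r"),
               rownames(m))
  out$n_meth <- as.integer(m[ord, 1L])
  out$n_unmeth <- as.integer(u[ord, 1L])
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}
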