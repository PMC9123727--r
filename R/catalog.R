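# Homoeologous gene-pair catalogue: reciprocal best hits filtered by an
# orthologous-chromosome-pair (OCP) assignment.

#' Reciprocal best hits between the two subgenome gene sets
#'
#' A pair (gene_R, gene_C) is kept iff each gene is the other's best hit and
#' both directions satisfy the filters: e-value below \code{max_evalue},
#' query coverage at least \code{min_coverage} and aligned (identical
#' segment) length at least \code{min_identity_len}. "Best" means highest
#' bitscore; bitscore ties are broken by higher percent identity, then
#' lexicographically by subject id for determinism.
#'
#' @param hits_RtoC,hits_CtoR hit tables from [read_hit_table()], queries in
#'   subgenome R (resp. C).
#' @param max_evalue,min_coverage,min_identity_len filter thresholds;
#'   defaults 1e-5, 0.80 and 300 bp.
#' @return data.frame with columns \code{gene_R}, \code{gene_C}.
#' @export
reciprocal_best_hits <- function(hits_RtoC, hits_CtoR, max_evalue = 1e-5,
                                 min_coverage = 0.80, min_identity_len = 300) {
  best <- function(h) {
    h <- h[h$evalue < max_evalue & h$q_cov >= min_coverage &
             h$aln_len >= min_identity_len, , drop = FALSE]
    if (!nrow(h)) {
      return(stats::setNames(character(0), character(0)))
    }
    o <- order(h$query, -h$bitscore, -h$identity, h$subject)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(h$query), , drop = FALSE]
    stats::setNames(h$subject, h$query)
  }
  rc <- best(hits_RtoC)
  cr <- best(hits_CtoR)
  gene_R <- names(rc)
  keep <- !is.na(cr[rc[gene_R]]) & cr[rc[gene_R]] == gene_R
  keep[is.na(keep)] <- FALSE
  out <- data.frame(gene_R = gene_R[keep], gene_C = unname(rc[gene_R[keep]]),
                    stringsAsFactors = FALSE)
  out[order(out$gene_R), , drop = FALSE]
}

#' Assign orthologous chromosome pairs by majority vote
#'
#' Counts candidate gene pairs per (chrom_R, chrom_C) combination and builds
#' a one-to-one chromosome matching greedily: repeatedly take the
#' combination with the largest count, assign it, and remove both
#' chromosomes. Ties are broken lexicographically by (chrom_R, chrom_C).
#' This is a deliberate simplification of collinearity-based orthologous
#' chromosome detection; see the methods vignette.
#'
#' @param pairs data.frame with columns \code{chrom_R}, \code{chrom_C} (one
#'   row per candidate gene pair, e.g. [add_pair_chromosomes()] output).
#' @return named character vector, chrom_R -> chrom_C.
#' @export
assign_orthologous_chromosomes <- function(pairs) {
  if (!nrow(pairs)) stop("need at least one pair to assign chromosomes")
  counts <- as.data.frame(table(chrom_R = pairs$chrom_R,
                                chrom_C = pairs$chrom_C),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0L, , drop = FALSE]
  counts <- counts[order(-counts$Freq, counts$chrom_R, counts$chrom_C), ,
                   drop = FALSE]
  ocp <- character(0)
  while (nrow(counts)) {
    top <- counts[1L, ]
    ocp[top$chrom_R] <- top$chrom_C
    counts <- counts[counts$chrom_R != top$chrom_R &
                       counts$chrom_C != top$chrom_C, , drop = FALSE]
  }
  ocp
}

#' Attach chromosome columns to RBH pairs
#' @param pairs output of [reciprocal_best_hits()].
#' @param genes gene models from [read_gene_annotation()] (both subgenomes).
#' @return \code{pairs} with added \code{chrom_R}, \code{chrom_C}.
#' @export
add_pair_chromosomes <- function(pairs, genes) {
  chrom <- stats::setNames(genes$chrom, genes$gene_id)
  missing <- setdiff(c(pairs$gene_R, pairs$gene_C), names(chrom))
  if (length(missing)) stop("gene not in annotation: ", missing[1L])
  pairs$chrom_R <- unname(chrom[pairs$gene_R])
  pairs$chrom_C <- unname(chrom[pairs$gene_C])
  pairs
}

#' Per-genotype homoeolog copy numbers
#'
#' The diploid parents carry two copies of their own subgenome and none of
#' the other; the triploids carry two copies of the duplicated subgenome and
#' one of the other (3nR2C = RRC, 3nRC2 = RCC).
#'
#' @param genotype one of \code{"2nRR"}, \code{"2nCC"}, \code{"3nR2C"},
#'   \code{"3nRC2"}.
#' @return integer vector \code{c(R = ..., C = ...)}.
#' @export
genotype_copy_numbers <- function(genotype) {
  switch(match.arg(genotype, GENOTYPES),
         "2nRR" = c(R = 2L, C = 0L),
         "2nCC" = c(R = 0L, C = 2L),
         "3nR2C" = c(R = 2L, C = 1L),
         "3nRC2" = c(R = 1L, C = 2L))
}

#' Build the homoeolog pair catalogue
#'
#' Keeps reciprocal-best-hit pairs whose chromosomes agree with the
#' orthologous-chromosome-pair table and records per-genotype copy numbers.
#'
#' @param pairs RBH pairs with \code{chrom_R}/\code{chrom_C} columns.
#' @param ocp named vector chrom_R -> chrom_C from
#'   [assign_orthologous_chromosomes()].
#' @return data.frame with \code{gene_R}, \code{gene_C}, \code{chrom_R},
#'   \code{chrom_C}, \code{ocp_id} and copy-number columns
#'   \code{copy_R_<genotype>}, \code{copy_C_<genotype>}.
#' @export
build_catalog <- function(pairs, ocp) {
  keep <- !is.na(ocp[pairs$chrom_R]) & ocp[pairs$chrom_R] == pairs$chrom_C
  keep[is.na(keep)] <- FALSE
  out <- pairs[keep, , drop = FALSE]
  out$ocp_id <- paste0(out$chrom_R, ":", out$chrom_C)
  for (g in GENOTYPES) {
    cn <- genotype_copy_numbers(g)
    out[[paste0("copy_R_", g)]] <- cn[["R"]]
    out[[paste0("copy_C_", g)]] <- cn[["C"]]
  }
  rownames(out) <- NULL
  out
}
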