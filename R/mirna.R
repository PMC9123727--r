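# miRNA module: exact-identity dedup, subgenome copy-number pattern
# classification, per-miRNA aggregation over loci, and miRNA DE.

#' Remove exact duplicate sequences
#'
#' Sequences are compared after uppercasing and U->T normalisation
#' (identity 1.0 means string equality); the first-seen id is kept.
#'
#' @param seqs named character vector of sequences (e.g. [read_fasta()]).
#' @return named character vector with duplicates removed (original
#'   sequence text of the first occurrence).
#' @export
dedup_exact <- function(seqs) {
  if (any(!nzchar(seqs))) {
    stop("empty sequence: ", names(seqs)[!nzchar(seqs)][1L])
  }
  norm <- chartr("uU", "tT", seqs)
  norm <- toupper(norm)
  seqs[!duplicated(norm)]
}

MIRNA_PATTERNS <- c("P1", "P2", "P3", "P4", "P5R", "P5C", "P6R", "P6C")

#' Classify a miRNA's subgenome copy-number pattern
#'
#' Patterns over (loci in R, loci in C): P1 = (2,2), P2 = (1,2),
#' P3 = (2,1), P4 = (1,1), P5R/P5C = two copies in only one subgenome,
#' P6R/P6C = a single subgenome-specific copy. Combinations outside the six
#' diagrams (any count above 2) are reported as \code{"other"} rather than
#' forced into a pattern. (0,0) is an error.
#'
#' @param n_R,n_C non-negative locus counts (vectorised).
#' @return character vector of pattern labels.
#' @export
classify_pattern <- function(n_R, n_C) {
  if (any(n_R + n_C < 1L)) stop("miRNA with zero loci in both subgenomes")
  key <- paste(n_R, n_C)
  map <- c("2 2" = "P1", "1 2" = "P2", "2 1" = "P3", "1 1" = "P4",
           "2 0" = "P5R", "0 2" = "P5C", "1 0" = "P6R", "0 1" = "P6C")
  out <- unname(map[key])
  out[is.na(out)] <- "other"
  out
}

#' Pattern assignments for a miRNA locus table
#' @param loci locus table from [read_mirna_loci()].
#' @return data.frame with \code{mirna_id}, \code{n_R}, \code{n_C},
#'   \code{pattern}.
#' @export
assign_patterns <- function(loci) {
  nr <- tapply(loci$subgenome == "R", loci$mirna_id, sum)
  nc <- tapply(loci$subgenome == "C", loci$mirna_id, sum)
  ids <- sort(unique(loci$mirna_id))
  data.frame(mirna_id = ids, n_R = as.integer(nr[ids]),
             n_C = as.integer(nc[ids]),
             pattern = classify_pattern(as.integer(nr[ids]),
                                        as.integer(nc[ids])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate locus-level counts to miRNA-level counts
#'
#' Per miRNA and sample, counts are summed over all of its loci in both
#' subgenomes (the copies are sequence-identical, so reads cannot be
#' attributed to a single locus).
#'
#' @param locus_counts counts matrix (locus x sample).
#' @param locus_mirna named character vector locus_id -> mirna_id covering
#'   every row.
#' @return counts matrix (mirna_id x sample).
#' @export
aggregate_expression <- function(locus_counts, locus_mirna) {
  unknown <- setdiff(rownames(locus_counts), names(locus_mirna))
  if (length(unknown)) stop("locus with unknown miRNA id: ", unknown[1L])
  out <- rowsum(locus_counts, unname(locus_mirna[rownames(locus_counts)]))
  md <- attr(locus_counts, "metadata")
  if (!is.null(md)) attr(out, "metadata") <- md
  out
}

#' miRNA differential expression
#'
#' Delegates to [call_de()] with the stricter miRNA FDR threshold of 0.01.
#' @param mat aggregated miRNA counts matrix.
#' @param group1,group2 sample columns of the two groups.
#' @param fdr FDR threshold, default 0.01.
#' @param ... forwarded to [call_de()].
#' @export
de_mirna <- function(mat, group1, group2, fdr = 0.01, ...) {
  call_de(mat, group1, group2, fdr = fdr, ...)
}
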