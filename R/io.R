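#' @keywords internal
"_PACKAGE"

GENOTYPES <- c("2nRR", "2nCC", "3nR2C", "3nRC2")

# context tokens as written in cytosine reports -> internal labels
.CONTEXT_MAP <- c(CG = "CpG", CHG = "CHG", CHH = "CHH")
.CONTEXT_REV <- c(CpG = "CG", CHG = "CHG", CHH = "CHH")

#' Read a per-cytosine methylation report
#'
#' Parses the tab-separated per-cytosine report dialect produced by bisulfite
#' callers (columns: chrom, 1-based position, strand, methylated count,
#' unmethylated count, context token, trinucleotide). Context tokens are
#' normalised: \code{CG} becomes \code{CpG}; \code{CHG}/\code{CHH} are kept.
#' An unknown token is a hard error rather than a silent skip, because it
#' almost always indicates a strand or context bug upstream.
#'
#' No coverage filtering happens here: every record is returned in file
#' order, and \code{min_coverage} is only attached as an attribute so that
#' downstream callers (e.g. [call_methylation()]) can pick it up.
#'
#' @param path path to the tab-separated report.
#' @param min_coverage minimum coverage intended by the caller; recorded as
#'   attribute \code{"min_coverage"}, never used to drop records.
#' @return a data.frame with columns \code{chrom}, \code{pos}, \code{strand},
#'   \code{context}, \code{n_meth}, \code{n_unmeth}.
#' @seealso [write_cytosine_report()]
#' @export
read_cytosine_report <- function(path, min_coverage = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- nzchar(raw)
  lineno <- which(keep)
  raw <- raw[keep]
  if (!length(raw)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      n_meth = integer(), n_unmeth = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "min_coverage") <- as.integer(min_coverage)
    return(out)
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    i <- which(nf != 7L)[1L]
    stop(sprintf("malformed cytosine report line %d in %s: expected 7 tab-separated fields, got %d",
                 lineno[i], path, nf[i]))
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 7L, byrow = TRUE)
  context <- unname(.CONTEXT_MAP[m[, 6L]])
  if (anyNA(context)) {
    i <- which(is.na(context))[1L]
    stop(sprintf("unknown context token '%s' at line %d of %s",
                 m[i, 6L], lineno[i], path))
  }
  pos <- suppressWarnings(as.integer(m[, 2L]))
  n_meth <- suppressWarnings(as.integer(m[, 4L]))
  n_unmeth <- suppressWarnings(as.integer(m[, 5L]))
  bad <- is.na(pos) | pos < 1L | is.na(n_meth) | n_meth < 0L |
    is.na(n_unmeth) | n_unmeth < 0L | !(m[, 3L] %in% c("+", "-"))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("malformed cytosine report line %d in %s", lineno[i], path))
  }
  out <- data.frame(chrom = m[, 1L], pos = pos, strand = m[, 3L],
                    context = context, n_meth = n_meth, n_unmeth = n_unmeth,
                    stringsAsFactors = FALSE)
  attr(out, "min_coverage") <- as.integer(min_coverage)
  out
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]; the trinucleotide column is filled
#' with a generic token per context.
#'
#' @param records data.frame as returned by [read_cytosine_report()].
#' @param path output path.
#' @export
write_cytosine_report <- function(records, path) {
  tri <- c(CpG = "CGN", CHG = "CHG", CHH = "CHH")[records$context]
  lines <- paste(records$chrom, records$pos, records$strand,
                 records$n_meth, records$n_unmeth,
                 .CONTEXT_REV[records$context], tri, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

.default_subgenome <- function(chrom) {
  out <- rep(NA_character_, length(chrom))
  out[startsWith(chrom, "R")] <- "R"
  out[startsWith(chrom, "C")] <- "C"
  out
}

#' Read gene models from GFF3 or BED12
#'
#' Returns gene models normalised to 1-based inclusive coordinates with
#' exons stored in transcript (5'->3') orientation, i.e. for minus-strand
#' genes the first exon has the largest genomic coordinates and
#' \code{tss > tts}.
#'
#' @param path annotation file.
#' @param dialect \code{"gff3"} (1-based inclusive, \code{gene}/\code{exon}
#'   features, \code{ID=}/\code{Parent=} attributes) or \code{"bed12"}
#'   (0-based half-open blocks).
#' @param subgenome_fun function mapping a chromosome name to a subgenome
#'   label; the default maps chromosomes starting with \code{R}/\code{C}.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tss}, \code{tts}, \code{start}, \code{end},
#'   \code{subgenome} and a list column \code{exons} (two-column matrix of
#'   1-based inclusive start/end per exon, ordered 5'->3').
#' @export
read_gene_annotation <- function(path, dialect = c("gff3", "bed12"),
                                 subgenome_fun = .default_subgenome) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  genes <- switch(dialect,
                  gff3 = .read_gff3_genes(path),
                  bed12 = .read_bed12_genes(path))
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in ", path, ": ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  n_ex <- vapply(genes$exons, nrow, integer(1))
  if (any(n_ex == 0L)) {
    stop("gene with zero exons: ", genes$gene_id[n_ex == 0L][1L])
  }
  # orient exons 5'->3' and set tss/tts from the gene span
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (genes$strand[i] == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    genes$exons[[i]] <- ex
  }
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  genes$tts <- ifelse(genes$strand == "-", genes$start, genes$end)
  genes$subgenome <- subgenome_fun(genes$chrom)
  genes[c("gene_id", "chrom", "strand", "tss", "tts", "start", "end",
          "subgenome", "exons")]
}

.read_gff3_genes <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) stop("malformed GFF3 line: expected 9 fields, got ", nf[nf != 9L][1L])
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 9L, byrow = TRUE)
  attr1 <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]+"), attrs))
    out <- rep(NA_character_, length(attrs))
    got <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    out[got] <- sub(paste0("^;?", key, "="), "", unlist(hit))
    out
  }
  type <- m[, 3L]
  gi <- type == "gene"
  ei <- type == "exon"
  gene_id <- attr1(m[gi, 9L], "ID")
  if (anyNA(gene_id)) stop("GFF3 gene feature without ID attribute")
  parent <- attr1(m[ei, 9L], "Parent")
  if (anyNA(parent)) stop("GFF3 exon feature without Parent attribute")
  ex_start <- as.integer(m[ei, 4L])
  ex_end <- as.integer(m[ei, 5L])
  exons <- lapply(gene_id, function(g) {
    sel <- parent == g
    cbind(start = ex_start[sel], end = ex_end[sel])
  })
  data.frame(gene_id = gene_id, chrom = m[gi, 1L], strand = m[gi, 7L],
             start = as.integer(m[gi, 4L]), end = as.integer(m[gi, 5L]),
             exons = I(exons), stringsAsFactors = FALSE)
}

.read_bed12_genes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 12L) stop("expected 12-column BED12, got ", ncol(tab), " columns")
  exons <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sizes <- as.integer(strsplit(sub(",$", "", tab[i, 11L]), ",")[[1L]])
    offs <- as.integer(strsplit(sub(",$", "", tab[i, 12L]), ",")[[1L]])
    if (length(sizes) != tab[i, 10L] || length(offs) != tab[i, 10L]) {
      stop("BED12 block count mismatch for ", tab[i, 4L])
    }
    # BED is 0-based half-open; internal coordinates 1-based inclusive
    st <- tab[i, 2L] + offs + 1L
    exons[[i]] <- cbind(start = st, end = st + sizes - 1L)
  }
  data.frame(gene_id = tab[, 4L], chrom = tab[, 1L], strand = tab[, 6L],
             start = tab[, 2L] + 1L, end = tab[, 3L],
             exons = I(exons), stringsAsFactors = FALSE)
}

#' Read a tabular pairwise hit table with query lengths
#'
#' Reads a 12-column tabular similarity-search layout (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bitscore) plus a two-column lengths table
#' (\code{id}, \code{length}) used to compute query coverage.
#'
#' @param path hit table path.
#' @param lengths_path two-column tab-separated id/length table; every query
#'   in the hit table must be present.
#' @return data.frame with columns \code{query}, \code{subject},
#'   \code{identity}, \code{aln_len}, \code{evalue}, \code{bitscore},
#'   \code{q_cov}.
#' @export
read_hit_table <- function(path, lengths_path) {
  empty <- data.frame(query = character(), subject = character(),
                      identity = numeric(), aln_len = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      q_cov = numeric(), stringsAsFactors = FALSE)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(empty)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (!nrow(tab)) return(empty)
  if (ncol(tab) != 12L) stop("expected 12-column hit table, got ", ncol(tab))
  len <- utils::read.table(lengths_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  qlen <- stats::setNames(as.numeric(len[, 2L]), len[, 1L])
  missing <- setdiff(tab[, 1L], names(qlen))
  if (length(missing)) {
    stop("missing query length for: ", missing[1L])
  }
  data.frame(query = tab[, 1L], subject = tab[, 2L],
             identity = as.numeric(tab[, 3L]),
             aln_len = as.integer(tab[, 4L]),
             evalue = as.numeric(tab[, 11L]),
             bitscore = as.numeric(tab[, 12L]),
             q_cov = as.integer(tab[, 4L]) / unname(qlen[tab[, 1L]]),
             stringsAsFactors = FALSE)
}

#' Parse a genotype label from a sample name
#'
#' Sample names follow \code{<genotype>_<replicate>}, e.g. \code{3nR2C_2}.
#' @param sample character vector of sample names.
#' @return data.frame with \code{sample}, \code{genotype}, \code{replicate}.
#' @export
parse_sample_names <- function(sample) {
  genotype <- sub("_[0-9]+$", "", sample)
  replicate <- as.integer(sub("^.*_", "", sample))
  bad <- !(genotype %in% GENOTYPES) | is.na(replicate)
  if (any(bad)) stop("cannot parse sample name: ", sample[bad][1L])
  data.frame(sample = sample, genotype = genotype, replicate = replicate,
             stringsAsFactors = FALSE)
}

#' Read a feature-by-sample count table
#'
#' First column is the feature id, header row carries sample names of the
#' form \code{<genotype>_<replicate>}. Per-sample metadata is attached as
#' attribute \code{"metadata"}.
#'
#' @param path tab-separated count table.
#' @return integer matrix (features x samples) with a \code{metadata}
#'   attribute as produced by [parse_sample_names()].
#' @export
read_count_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab)
  storage.mode(mat) <- "integer"
  if (any(mat < 0L)) stop("negative count in ", path)
  attr(mat, "metadata") <- parse_sample_names(colnames(mat))
  mat
}

#' Write a feature-by-sample count table
#' @param mat integer matrix with feature row names and sample column names.
#' @param path output path.
#' @param id_col header name of the feature-id column.
#' @export
write_count_table <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA locus table
#'
#' Tab-separated with header \code{mirna_id, subgenome, chrom, start, end,
#' strand}.
#' @param path locus table path.
#' @export
read_mirna_loci <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("mirna_id", "subgenome", "chrom", "start", "end", "strand")
  if (!all(need %in% colnames(tab))) {
    stop("miRNA locus table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(tab$subgenome %in% c("R", "C"))) stop("subgenome must be R or C")
  tab[need]
}

#' Read intervals from a BED3/BED6 file
#'
#' Coordinates are converted from BED's 0-based half-open convention to the
#' package-wide 1-based inclusive convention. Strand defaults to \code{+}
#' when absent (BED3).
#' @param path BED file.
#' @export
read_bed_intervals <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = tab[, 1L], start = tab[, 2L] + 1L, end = tab[, 3L],
             strand = if (ncol(tab) >= 6L) tab[, 6L] else "+",
             stringsAsFactors = FALSE)
}

#' Read sequences from a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a named character vector of sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
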