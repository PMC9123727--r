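# Shared fixtures, all generated in code.

tiny_scenario <- function(...) {
  defaults <- list(seed = 11, n_chrom_pairs = 2, genes_per_chrom = 12,
                   cpgs_per_promoter = 8, cpgs_per_body = 6,
                   n_recombined_genes = 3, n_te_per_chrom = 2,
                   mirna_pattern_counts = c(P1 = 3L, P2 = 2L, P3 = 2L,
                                            P4 = 2L, P5R = 1L, P5C = 1L,
                                            P6R = 2L, P6C = 1L))
  do.call(sim_scenario, utils::modifyList(defaults, list(...)))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# small cytosine-record data.frame builder
cyt <- function(chrom, pos, n_meth, n_unmeth, strand = "+",
                context = "CpG") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             n_meth = n_meth, n_unmeth = n_unmeth, stringsAsFactors = FALSE)
}

# deterministic NB count matrix for expression tests
nb_matrix <- function(n_features, mu, dispersion, n_samples, seed,
                      prefix = c("3nR2C", "2nRR")) {
  set.seed(seed)
  if (length(mu) == 1L) {
    mu <- stats::rlnorm(n_features, log(mu), 1)
  }
  mat <- sapply(seq_len(n_samples), function(j)
    stats::rnbinom(n_features, size = 1 / dispersion, mu = mu))
  rownames(mat) <- sprintf("g%04d", seq_len(n_features))
  colnames(mat) <- paste0(rep(prefix, each = n_samples / 2),
                          "_", rep(seq_len(n_samples / 2), 2))
  mat
}
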