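# Promoter methylation divergence: parental vs within-triploid homoeolog
# divergence, hyper/hypo classification and prediction of homoeologous
# recombinant genes (HRGs).

#' Promoter methylation divergence per homoeolog pair
#'
#' For each pair, the parental divergence is
#' \code{d_parent = level(gene_R in 2nRR) - level(gene_C in 2nCC)} and the
#' triploid divergence is \code{level(homoeolog R) - level(homoeolog C)}
#' within each triploid. Pairs with an undefined promoter level in any
#' genotype are dropped; the number dropped is attached as attribute
#' \code{"n_dropped"}.
#'
#' @param pairs homoeolog catalogue (needs \code{gene_R}, \code{gene_C}).
#' @param levels_by_genotype named list (\code{2nRR}, \code{2nCC},
#'   \code{3nR2C}, \code{3nRC2}) of named vectors gene_id -> promoter level,
#'   e.g. from [promoter_levels()] on replicate-pooled records.
#' @return data.frame with \code{gene_R}, \code{gene_C}, \code{d_parent},
#'   \code{d_3nR2C}, \code{d_3nRC2}.
#' @export
compute_divergence <- function(pairs, levels_by_genotype) {
  need <- c("2nRR", "2nCC", "3nR2C", "3nRC2")
  if (!all(need %in% names(levels_by_genotype))) {
    stop("levels_by_genotype must have entries: ", paste(need, collapse = ", "))
  }
  lv <- levels_by_genotype
  pick <- function(v, ids) {
    out <- rep(NA_real_, length(ids))
    hit <- ids %in% names(v)
    out[hit] <- v[ids[hit]]
    out
  }
  d_parent <- pick(lv[["2nRR"]], pairs$gene_R) - pick(lv[["2nCC"]], pairs$gene_C)
  d_r2c <- pick(lv[["3nR2C"]], pairs$gene_R) - pick(lv[["3nR2C"]], pairs$gene_C)
  d_rc2 <- pick(lv[["3nRC2"]], pairs$gene_R) - pick(lv[["3nRC2"]], pairs$gene_C)
  out <- data.frame(gene_R = pairs$gene_R, gene_C = pairs$gene_C,
                    d_parent = d_parent, d_3nR2C = d_r2c, d_3nRC2 = d_rc2,
                    stringsAsFactors = FALSE)
  ok <- stats::complete.cases(out[c("d_parent", "d_3nR2C", "d_3nRC2")])
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(!ok)
  res
}

#' Classify a homoeolog pair as hyper-/hypo-DMG
#'
#' Thresholds apply to absolute divergences; signs are kept elsewhere for
#' direction. For one triploid: \emph{hyper} iff the parental divergence
#' exceeds \code{hyper_parent} while the triploid homoeolog divergence has
#' collapsed below \code{hyper_triploid}; \emph{hypo} iff the parental
#' divergence is between \code{hypo_parent_lower} (exclusive) and
#' \code{hyper_parent} (exclusive) and the triploid divergence is below
#' \code{hypo_triploid}; otherwise \emph{none}. \code{hypo_parent_lower}
#' defaults to 0 (the procedural definition); setting it to 0.4 reproduces
#' the narrower variant used in some summaries.
#'
#' @param d_parent,d_triploid signed divergences (vectorised).
#' @param hyper_parent,hyper_triploid,hypo_triploid,hypo_parent_lower
#'   thresholds; defaults 0.6 / 0.3 / 0.2 / 0.
#' @return character vector in \{"hyper", "hypo", "none"\}.
#' @export
classify_dmg <- function(d_parent, d_triploid, hyper_parent = 0.6,
                         hyper_triploid = 0.3, hypo_triploid = 0.2,
                         hypo_parent_lower = 0) {
  ap <- abs(d_parent)
  at <- abs(d_triploid)
  out <- rep("none", length(ap))
  out[ap > hyper_parent & at < hyper_triploid] <- "hyper"
  out[ap > hypo_parent_lower & ap < hyper_parent & at < hypo_triploid] <- "hypo"
  out
}

#' Predict homoeologous recombinant genes shared by both triploids
#'
#' Runs [classify_dmg()] per triploid and flags a pair as a candidate HRG
#' when its class is identical and non-none in \emph{both} triploids: a
#' promoter exchange inherited from the tetraploid ancestor collapses the
#' homoeolog methylation divergence in both derived triploids at once.
#'
#' @param divergence output of [compute_divergence()].
#' @param ... threshold arguments forwarded to [classify_dmg()].
#' @return \code{divergence} with added columns \code{class_3nR2C},
#'   \code{class_3nRC2}, \code{dmg_class} (the shared class or "none") and
#'   \code{is_hrg}.
#' @export
predict_hrgs <- function(divergence, ...) {
  divergence$class_3nR2C <- classify_dmg(divergence$d_parent,
                                         divergence$d_3nR2C, ...)
  divergence$class_3nRC2 <- classify_dmg(divergence$d_parent,
                                         divergence$d_3nRC2, ...)
  shared <- divergence$class_3nR2C == divergence$class_3nRC2 &
    divergence$class_3nR2C != "none"
  divergence$dmg_class <- ifelse(shared, divergence$class_3nR2C, "none")
  divergence$is_hrg <- shared
  divergence
}
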