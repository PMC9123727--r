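# Homoeologous-recombination detection from resequencing read depth:
# per-pair log10 R/C length-normalised read-density ratio against the
# analytic copy-number reference line and significance boundaries.

#' Analytic reference value of the log10 homoeolog read-depth ratio
#'
#' For an unrecombined pair the expected length-normalised read-density
#' ratio equals the copy-number ratio, so the reference line is
#' \code{log10(copy_R / copy_C)}: 0.30103 for the genotype carrying two R
#' and one C copy, -0.30103 for the reciprocal genotype.
#'
#' @param copy_R,copy_C positive integer copy numbers (vectorised).
#' @return log10 copy-number ratio.
#' @export
expected_log_ratio <- function(copy_R, copy_C) {
  if (any(copy_R <= 0L) || any(copy_C <= 0L)) {
    stop("copy numbers must be positive: the reference ratio is undefined at zero copies")
  }
  log10(copy_R / copy_C)
}

#' Significance boundaries around the reference log-ratio
#'
#' The band is the reference value plus/minus \code{halfwidth}, by default
#' log10(2) (a two-fold departure from the expected copy ratio, i.e. one
#' exchanged copy). For copies (2,1) this reproduces the printed lines 0 and
#' 0.60206; for (1,2), -0.60206 and 0.
#'
#' @param copy_R,copy_C positive copy numbers.
#' @param halfwidth half-width of the band on the log10 scale.
#' @return list with \code{lower} and \code{upper}.
#' @export
default_boundaries <- function(copy_R, copy_C, halfwidth = log10(2)) {
  e <- expected_log_ratio(copy_R, copy_C)
  list(lower = e - halfwidth, upper = e + halfwidth)
}

#' Call unequal homoeologous recombination from read-depth ratios
#'
#' Per pair the read density is reads per kb of gene length; the statistic
#' is \code{log10(density_R / density_C)}, compared with the genotype's
#' reference line and boundaries. Pairs with total reads below
#' \code{min_reads} are reported with an undefined ratio and never flagged.
#' Pairs with exactly one zero side are reported in the one-sided channel
#' (\code{one_sided = TRUE}) rather than given a pseudocount: a 3:0 pattern
#' is a real event but its ratio is unbounded.
#'
#' @param pairs data.frame with columns \code{reads_R}, \code{reads_C},
#'   \code{len_R}, \code{len_C} (and any id columns, which are carried
#'   through).
#' @param genotype triploid genotype, \code{"3nR2C"} or \code{"3nRC2"},
#'   fixing the copy numbers; alternatively pass \code{copy_R}/\code{copy_C}.
#' @param min_reads minimum total reads for a defined ratio.
#' @param copy_R,copy_C copy numbers, defaulting to the genotype's.
#' @param halfwidth passed to [default_boundaries()].
#' @return \code{pairs} with added \code{log_ratio}, \code{expected},
#'   \code{lower}, \code{upper}, \code{flagged}, \code{one_sided}.
#' @export
call_hr <- function(pairs, genotype = c("3nR2C", "3nRC2"), min_reads = 20L,
                    copy_R = NULL, copy_C = NULL, halfwidth = log10(2)) {
  if (is.null(copy_R) || is.null(copy_C)) {
    cn <- genotype_copy_numbers(match.arg(genotype))
    copy_R <- cn[["R"]]
    copy_C <- cn[["C"]]
  }
  if (any(pairs$reads_R < 0L) || any(pairs$reads_C < 0L)) {
    stop("negative read counts")
  }
  stopifnot(all(pairs$len_R > 0), all(pairs$len_C > 0))
  b <- default_boundaries(copy_R, copy_C, halfwidth)
  dens_R <- pairs$reads_R / (pairs$len_R / 1000)
  dens_C <- pairs$reads_C / (pairs$len_C / 1000)
  total <- pairs$reads_R + pairs$reads_C
  defined <- total >= min_reads & pairs$reads_R > 0L & pairs$reads_C > 0L
  lr <- rep(NA_real_, nrow(pairs))
  lr[defined] <- log10(dens_R[defined] / dens_C[defined])
  pairs$log_ratio <- lr
  pairs$expected <- expected_log_ratio(copy_R, copy_C)
  pairs$lower <- b$lower
  pairs$upper <- b$upper
  pairs$flagged <- defined & (lr < b$lower | lr > b$upper)
  pairs$flagged[is.na(pairs$flagged)] <- FALSE
  pairs$one_sided <- total >= min_reads & xor(pairs$reads_R == 0L,
                                              pairs$reads_C == 0L)
  pairs
}

# tricube kernel on |u| < 1
.tricube <- function(u) {
  w <- (1 - abs(u)^3)^3
  w[abs(u) >= 1] <- 0
  w
}

#' Smoothed positional trend of the log read-depth ratio
#'
#' Local linear regression with tricube weights over the nearest
#' \code{floor(span * n)} neighbours, evaluated at every input position
#' (loess-style first-degree smoothing, deterministic).
#'
#' @param position genomic positions (numeric).
#' @param log_ratio defined log10 ratios, same length; \code{NA}s are
#'   dropped pairwise.
#' @param span fraction of points in each local neighbourhood, default 0.3.
#' @return data.frame with \code{position} and \code{trend}, ordered by
#'   position.
#' @export
trend_line <- function(position, log_ratio, span = 0.3) {
  ok <- is.finite(position) & is.finite(log_ratio)
  x <- position[ok]
  y <- log_ratio[ok]
  n <- length(x)
  if (n < 10L) stop("need at least 10 defined ratios for a trend line")
  o <- order(x)
  x <- x[o]
  y <- y[o]
  q <- max(2L, min(n, floor(span * n)))
  trend <- vapply(x, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    if (h <= 0) h <- max(d, .Machine$double.eps)
    w <- .tricube(d / h)
    if (sum(w > 0) < 2L) w <- pmax(w, .Machine$double.eps)
    xc <- x - x0
    sw <- sum(w)
    mx <- sum(w * xc) / sw
    my <- sum(w * y) / sw
    sxx <- sum(w * (xc - mx)^2)
    if (sxx <= 0) return(my)
    beta <- sum(w * (xc - mx) * (y - my)) / sxx
    my - beta * mx  # fitted value at xc = 0
  }, numeric(1))
  data.frame(position = x, trend = trend)
}
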