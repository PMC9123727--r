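# Homoeolog expression: low-count filtering, TMM normalisation, a
# negative-binomial exact test for differential expression, and the
# x1/x2/x4 dosage-compensation scaling test.

#' Drop features below a count threshold in every sample
#'
#' A feature is removed when its count is below \code{min_count} in every
#' retained sample; the number removed is attached as attribute
#' \code{"n_removed"}.
#'
#' @param mat counts matrix (features x samples).
#' @param min_count threshold, default 5.
#' @export
filter_low_counts <- function(mat, min_count = 5L) {
  if (!nrow(mat)) {
    attr(mat, "n_removed") <- 0L
    return(mat)
  }
  keep <- apply(mat, 1L, function(x) any(x >= min_count))
  out <- mat[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "metadata") <- attr(mat, "metadata")
  out
}

#' Trimmed-mean-of-M-values (TMM) normalisation factors
#'
#' The reference sample is the one whose library-size-scaled upper quartile
#' is closest to the mean upper quartile. For each sample, M (log2 ratio vs
#' reference) and A (average log2 abundance) values are computed on features
#' positive in both; the 30 percent most extreme M and 5 percent most
#' extreme A values are trimmed (15 / 2.5 percent per tail) and the factor
#' is two to the power of the weighted mean of the remaining M values, with
#' inverse asymptotic (binomial) variances as weights. Factors are scaled to
#' geometric mean one.
#'
#' @param mat counts matrix with no all-zero samples.
#' @param logratio_trim total fraction of M values trimmed (0.3 = 15
#'   percent per tail).
#' @param sum_trim total fraction of A values trimmed.
#' @return numeric vector of per-sample normalisation factors.
#' @export
tmm_factors <- function(mat, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(mat)
  if (any(lib == 0)) stop("sample with zero library size")
  f75 <- vapply(seq_len(ncol(mat)), function(j)
    stats::quantile(mat[, j], 0.75) / lib[j], numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(mat)), function(j) {
    .tmm_pair(mat[, j], mat[, ref], lib[j], lib[ref],
              logratio_trim, sum_trim)
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  unname(factors)
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  ok <- obs > 0 & ref > 0
  obs <- obs[ok]
  ref <- ref[ok]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  # inverse of the delta-method (binomial) variance of M
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  2^f
}

#' Counts per million with normalisation factors
#' @param mat counts matrix.
#' @param factors per-sample factors, e.g. from [tmm_factors()].
#' @export
cpm <- function(mat, factors = tmm_factors(mat)) {
  t(t(mat) / (colSums(mat) * factors)) * 1e6
}

# Method-of-moments common NB dispersion on library-size-equalised counts.
.common_dispersion <- function(z, groups) {
  phi <- apply(z, 1L, function(y) {
    ms <- tapply(y, groups, mean)
    vs <- tapply(y, groups, stats::var)
    m <- mean(ms)
    v <- stats::weighted.mean(vs, tapply(y, groups, length) - 1L)
    if (!is.finite(v) || m <= 0) return(NA_real_)
    (v - m) / m^2
  })
  phi <- phi[is.finite(phi)]
  if (!length(phi)) return(1e-4)
  max(1e-4, stats::median(phi))
}

# Exact NB test conditional on the two-group sum (equal effective library
# sizes assumed after count equalisation).
.nb_exact_p <- function(yA, yB, nA, nB, phi) {
  s <- yA + yB
  if (s == 0) return(1)
  mu <- s / (nA + nB)
  k <- 0:s
  logp <- stats::dnbinom(k, size = nA / phi, mu = nA * mu, log = TRUE) +
    stats::dnbinom(s - k, size = nB / phi, mu = nB * mu, log = TRUE)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[yA + 1] * (1 + 1e-8)])
}

#' Differential expression with a common-dispersion NB exact test
#'
#' Counts are TMM-normalised; a common negative-binomial dispersion is
#' estimated by the method of moments on library-size-equalised counts, and
#' each feature is tested with an exact NB test conditional on the pooled
#' two-group sum. P-values are BH-corrected; a feature is called DE when
#' |log2 fold change| exceeds \code{lfc} and the q-value is below
#' \code{fdr}. The fold change is first-named over second-named group mean
#' CPM with a pseudocount of 0.5.
#'
#' @param mat counts matrix.
#' @param group1,group2 column names or indices of the two groups (>= 2
#'   replicates each).
#' @param fdr FDR threshold (0.05 for mRNA; use 0.01 for miRNA).
#' @param lfc log2 fold-change threshold, default 1.
#' @return data.frame with \code{feature}, \code{log2fc}, \code{p_value},
#'   \code{q_value}, \code{is_de}.
#' @export
call_de <- function(mat, group1, group2, fdr = 0.05, lfc = 1) {
  sub <- mat[, c(group1, group2), drop = FALSE]
  nA <- length(group1)
  nB <- length(group2)
  stopifnot(nA >= 2L, nB >= 2L)
  groups <- rep(c("A", "B"), c(nA, nB))
  f <- tmm_factors(sub)
  eff <- colSums(sub) * f
  # equalise to the geometric-mean effective library size
  target <- exp(mean(log(eff)))
  z <- t(t(sub) * (target / eff))
  phi <- .common_dispersion(z, groups)
  yA <- round(rowSums(z[, groups == "A", drop = FALSE]))
  yB <- round(rowSums(z[, groups == "B", drop = FALSE]))
  p <- vapply(seq_len(nrow(sub)), function(i)
    .nb_exact_p(yA[i], yB[i], nA, nB, phi), numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  xp <- cpm(sub, f)
  m1 <- rowMeans(xp[, seq_len(nA), drop = FALSE])
  m2 <- rowMeans(xp[, nA + seq_len(nB), drop = FALSE])
  log2fc <- log2((m1 + 0.5) / (m2 + 0.5))
  data.frame(feature = rownames(sub), log2fc = log2fc, p_value = p,
             q_value = q, is_de = abs(log2fc) > lfc & q < fdr,
             dispersion = phi, row.names = NULL, stringsAsFactors = FALSE)
}

#' Dosage-compensation scaling test
#'
#' For each scale k, the in-silico scaled triploid subgenome expression
#' log2(k * x + 1) is compared with the parental expression log2(y + 1)
#' over genes matched through the homoeolog catalogue. The verdict is
#' \emph{equal} when p > alpha, otherwise \emph{lower}/\emph{higher} by the
#' sign of the mean difference. A fully compensated subgenome is expected
#' to read lower at x1, equal at x2 and higher at x4.
#'
#' Expression values should be whole-library CPM: normalising within the
#' tested subgenome (or TMM between the triploid and the parent) removes
#' precisely the global dosage shift the test is after.
#'
#' @param x_triploid,x_parent matched per-gene mean CPM vectors (triploid
#'   subgenome and corresponding parent).
#' @param scales scaling factors, default c(1, 2, 4).
#' @param alpha significance level for the verdict.
#' @param mode \code{"welch"} (two-sample comparison of the two per-gene
#'   value distributions, default) or \code{"paired"} (t-test on per-gene
#'   differences; very powerful, and therefore sensitive to small
#'   library-composition offsets unrelated to dosage).
#' @return data.frame with \code{scale}, \code{mean_diff},
#'   \code{t_statistic}, \code{p_value}, \code{verdict}.
#' @export
dosage_scaling_test <- function(x_triploid, x_parent, scales = c(1, 2, 4),
                                alpha = 0.05, mode = c("welch", "paired")) {
  mode <- match.arg(mode)
  ok <- is.finite(x_triploid) & is.finite(x_parent)
  x <- x_triploid[ok]
  y <- x_parent[ok]
  if (length(x) < 10L) stop("need at least 10 matched genes")
  out <- lapply(scales, function(k) {
    a <- log2(k * x + 1)
    b <- log2(y + 1)
    d <- a - b
    if (mode == "paired") {
      if (stats::sd(d) == 0) {
        tt <- list(statistic = c(t = if (mean(d) == 0) 0 else Inf * sign(mean(d))),
                   p.value = if (mean(d) == 0) 1 else 0)
      } else {
        tt <- stats::t.test(d)
      }
    } else {
      tt <- stats::t.test(a, b)
    }
    verdict <- if (tt$p.value > alpha) "equal"
               else if (mean(d) < 0) "lower" else "higher"
    data.frame(scale = k, mean_diff = mean(d),
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean CPM per gene over a set of samples
#' @param mat counts matrix.
#' @param samples column names/indices to average over.
#' @param factors optional normalisation factors for the full matrix.
#' @export
mean_cpm <- function(mat, samples, factors = tmm_factors(mat)) {
  x <- cpm(mat, factors)[, samples, drop = FALSE]
  rowMeans(x)
}
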