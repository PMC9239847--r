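## Inference layer: maximum-statistic randomization tests on surrogate MI
## distributions, label-permutation Wilcoxon signed-rank comparisons,
## Kruskal-Wallis omnibus tests with Tukey-Kramer post hoc comparisons, and
## Benjamini-Hochberg FDR control.

#' Build a maximum null distribution from surrogate MI values
#'
#' Pools surrogate values across all dimensions except frequency band,
#' keeps the largest `n_keep` values, and takes their `prob` quantile as
#' the corrected significance threshold.  With the defaults this implements
#' a one-sided randomization test at p < 0.01 corrected for all pooled
#' dimensions.
#'
#' @param surrogates numeric vector of pooled surrogate values for one
#'   band, or a data.frame with columns `band` and `value` (one null per
#'   band is returned).
#' @param n_keep number of largest values retained (default 2000).
#' @param prob quantile of the retained values used as threshold
#'   (default 0.99).
#' @return object of class `max_null` (or a named list of them, one per
#'   band) with elements `values`, `threshold`, `n_pooled`.
#' @export
build_max_null <- function(surrogates, n_keep = 2000, prob = 0.99) {
  if (is.data.frame(surrogates)) {
    stopifnot(all(c("band", "value") %in% names(surrogates)))
    out <- lapply(split(surrogates$value, surrogates$band),
                  build_max_null, n_keep = n_keep, prob = prob)
    return(out)
  }
  v <- as.numeric(surrogates)
  n_pooled <- length(v)
  if (n_pooled == 0L) stop("build_max_null: no surrogate values", call. = FALSE)
  if (n_pooled < n_keep) {
    warning(sprintf("build_max_null: only %d pooled surrogates (< %d); using all", n_pooled, n_keep))
    kept <- sort(v, decreasing = TRUE)
  } else {
    kept <- sort(v, decreasing = TRUE)[seq_len(n_keep)]
  }
  structure(list(values = kept,
                 threshold = as.numeric(stats::quantile(kept, prob)),
                 n_pooled = n_pooled, prob = prob),
            class = "max_null")
}

#' @export
print.max_null <- function(x, ...) {
  cat(sprintf("<max_null> threshold (p%.0f of top %d / %d pooled): %.5f\n",
              100 * x$prob, length(x$values), x$n_pooled, x$threshold))
  invisible(x)
}

#' Test a group-level median against a maximum null threshold
#'
#' Significant iff the median of the per-participant values strictly
#' exceeds the null threshold (one-sided corrected randomization test).
#'
#' @param values numeric vector of per-participant estimates (>= 3).
#' @param null a `max_null` object.
#' @return list with `statistic` (the median), `threshold`, `significant`.
#' @export
test_group_median <- function(values, null) {
  stopifnot(inherits(null, "max_null"))
  if (length(values) < 3L) stop("test_group_median: need at least 3 participants", call. = FALSE)
  med <- stats::median(values)
  list(statistic = med, threshold = null$threshold,
       significant = med > null$threshold)
}

#' Wilcoxon signed-rank z statistic
#'
#' Paired signed-rank statistic with zero-difference dropping, tie-corrected
#' variance and (optionally) continuity correction, standardized to z.
#'
#' @param a,b paired numeric vectors.
#' @param continuity apply the 0.5 continuity correction (default TRUE).
#' @return z value (0 when all differences are zero).
#' @export
wilcoxon_signed_z <- function(a, b, continuity = TRUE) {
  d <- a - b
  d <- d[d != 0]
  nz <- length(d)
  if (nz == 0L) return(0)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- nz * (nz + 1) / 4
  ties <- table(r)
  sig2 <- nz * (nz + 1) * (2 * nz + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(0)
  num <- w - mu
  if (continuity) num <- num - sign(num) * 0.5
  num / sqrt(sig2)
}

#' Permutation Wilcoxon signed-rank test with maximum-statistic correction
#'
#' For each comparison (column) the true Wilcoxon z between the paired
#' samples is computed; the null is built by randomly permuting the pair
#' labels (sign flips of the differences) `n_perm` times jointly across the
#' whole correction scope and taking the per-permutation maximum |z|.  A
#' comparison is significant when its |z| exceeds the `1 - alpha` quantile
#' of that maximum distribution.  P-values are reported as (r+1)/(n+1) and
#' are never exactly zero.
#'
#' @param a,b paired numeric matrices (participants x comparisons) or
#'   vectors for a single comparison.  Columns define the correction scope.
#' @param n_perm number of label permutations (default 5000).
#' @param alpha significance level (default 0.01).
#' @param statistic "abs_z" (two-sided maximum, default) or "z" (signed).
#' @param seed optional integer seed.
#' @return data.frame of class `group_test` with one row per comparison:
#'   `statistic` (z), `p` (max-corrected), `significant`, plus the
#'   `threshold` attribute.
#' @export
permutation_wilcoxon_paired <- function(a, b, n_perm = 5000, alpha = 0.01,
                                        statistic = c("abs_z", "z"),
                                        seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.matrix(a)) a <- matrix(a, ncol = 1L)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1L)
  stopifnot(identical(dim(a), dim(b)))
  n <- nrow(a); m <- ncol(a)
  true_z <- vapply(seq_len(m), function(j) wilcoxon_signed_z(a[, j], b[, j]), 0)
  stat <- function(z) if (statistic == "abs_z") abs(z) else z
  d <- a - b
  zeros <- numeric(n)
  run_perms <- function() {
    vapply(seq_len(n_perm), function(r) {
      flip <- sample(c(-1, 1), n, replace = TRUE)
      max(vapply(seq_len(m), function(j)
        stat(wilcoxon_signed_z(flip * d[, j], zeros)), 0))
    }, 0)
  }
  perm_max <- if (is.null(seed)) run_perms() else with_seed(seed, run_perms())
  thr <- as.numeric(stats::quantile(perm_max, 1 - alpha))
  p <- vapply(stat(true_z), function(s) (sum(perm_max >= s) + 1) / (n_perm + 1), 0)
  out <- data.frame(comparison = if (!is.null(colnames(a))) colnames(a) else seq_len(m),
                    statistic = true_z, p = p,
                    significant = stat(true_z) > thr & stat(true_z) != 0)
  attr(out, "threshold") <- thr
  attr(out, "n_perm") <- n_perm
  class(out) <- c("group_test", "data.frame")
  out
}

#' Kruskal-Wallis rank test with Tukey-Kramer post hoc comparisons
#'
#' Omnibus rank-based chi-square (tie-corrected, via [stats::kruskal.test()])
#' with the rank epsilon-squared effect size chi^2/(n-1), followed by
#' Tukey-Kramer comparisons on the group mean ranks using the studentized
#' range distribution with the harmonic-mean sample-size correction.
#'
#' @param values numeric vector of observations.
#' @param groups factor or vector of group labels (k >= 3 levels, each with
#'   at least 2 observations).
#' @param alpha significance level (default 0.01).
#' @return list with `statistic` (chi-square), `df`, `p`, `epsilon_sq`, and
#'   `posthoc` (data.frame of pairwise rank-mean differences, q statistics,
#'   p-values and decisions).
#' @export
kruskal_wallis_posthoc <- function(values, groups, alpha = 0.01) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 3L) stop("kruskal_wallis_posthoc: need at least 3 groups", call. = FALSE)
  cnt <- table(groups)
  if (any(cnt < 2L)) stop("kruskal_wallis_posthoc: every group needs >= 2 observations", call. = FALSE)
  kt <- stats::kruskal.test(values, groups)
  n <- length(values)
  eps2 <- unname(kt$statistic) / (n - 1)
  ## Tukey-Kramer on mean ranks, tie-corrected variance
  r <- rank(values)
  ties <- table(r)
  mr <- tapply(r, groups, mean)
  v0 <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  combs <- utils::combn(levels(groups), 2)
  post <- do.call(rbind, lapply(seq_len(ncol(combs)), function(ci) {
    g1 <- combs[1, ci]; g2 <- combs[2, ci]
    se <- sqrt(v0 * (1 / cnt[g1] + 1 / cnt[g2]))
    q <- abs(mr[g1] - mr[g2]) / se * sqrt(2)
    data.frame(group1 = g1, group2 = g2,
               diff_rank = unname(mr[g1] - mr[g2]),
               q = unname(q),
               p = stats::ptukey(unname(q), k, Inf, lower.tail = FALSE))
  }))
  post$significant <- post$p < alpha
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, epsilon_sq = eps2, posthoc = post,
       significant = kt$p.value < alpha)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up BH procedure at level `q`; decisions and monotone adjusted
#' p-values.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.01).
#' @return data.frame with `p`, `p_adjusted`, `significant` in the input
#'   order (empty input gives an empty frame).
#' @export
bh_fdr <- function(pvals, q = 0.01) {
  if (length(pvals) == 0L)
    return(data.frame(p = numeric(0), p_adjusted = numeric(0), significant = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("bh_fdr: p-values outside [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, p_adjusted = adj, significant = adj <= q)
}
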