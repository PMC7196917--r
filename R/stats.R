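#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact test by the probability-mass rule (the p-value sums the
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table). The odds ratio is
#' the sample cross-product `ad/bc`; when any cell is zero the Haldane
#' correction adds 0.5 to every cell before forming the ratio, and the result
#' is flagged.
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts.
#' @return A list with `odds_ratio`, `p_value`, `conf_int` (exact 95%
#'   confidence interval for the odds ratio), and `haldane` (logical; `TRUE`
#'   when the 0.5 correction was applied).
#' @examples
#' fisher_exact_2x2(matrix(c(5, 2, 21, 94), nrow = 2))
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) {
    stop("`table` must be 2x2")
  }
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers")
  }
  ft <- stats::fisher.test(m)
  haldane <- any(m == 0)
  mm <- if (haldane) m + 0.5 else m
  or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  list(
    odds_ratio = unname(or),
    p_value = ft$p.value,
    conf_int = as.numeric(ft$conf.int),
    haldane = haldane
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with enforced monotonicity; the
#' input order is preserved in the output.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Rank-based group comparison
#'
#' Kruskal-Wallis omnibus test across two or more groups (tie-corrected H
#' with a chi-square approximation on k - 1 degrees of freedom). For exactly
#' two groups the two-sided Mann-Whitney p-value is also reported: exact by
#' enumeration when both group sizes are at most 8 and the data are free of
#' ties, and the tie/continuity-corrected normal approximation otherwise.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return list with `statistic` (H), `df`, `p_value`, and `mann_whitney_p`
#'   (`NA` unless exactly two groups were supplied).
#' @export
rank_group_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least two numeric vectors")
  }
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("all groups must be non-empty")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(x) < 3L) stop("need at least 3 observations in total")
  k <- length(groups)
  if (length(unique(x)) == 1L) {
    # all observations identical: H is 0 by construction
    res <- list(statistic = 0, df = k - 1L, p_value = 1)
  } else {
    kw <- stats::kruskal.test(x, g)
    res <- list(
      statistic = unname(kw$statistic),
      df = unname(kw$parameter),
      p_value = kw$p.value
    )
  }
  res$mann_whitney_p <- NA_real_
  if (k == 2L) {
    n1 <- length(groups[[1L]])
    n2 <- length(groups[[2L]])
    exact <- n1 <= 8L && n2 <= 8L && !any(duplicated(x))
    wt <- suppressWarnings(
      stats::wilcox.test(groups[[1L]], groups[[2L]],
        exact = exact, correct = TRUE
      )
    )
    res$mann_whitney_p <- wt$p.value
    if (length(unique(x)) == 1L) res$mann_whitney_p <- 1
  }
  res
}

#' Pearson chi-square test of independence
#'
#' Rows and columns whose margin is zero are dropped (and flagged) before the
#' statistic is formed; no continuity correction is applied.
#'
#' @param table r x c matrix of non-negative counts.
#' @return list with `statistic`, `df`, `p_value`, `dropped_rows`,
#'   `dropped_cols` (labels or indices of zero-margin rows/columns removed).
#' @export
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (anyNA(m) || any(m < 0)) stop("counts must be non-negative")
  rs <- rowSums(m)
  cs <- colSums(m)
  dropped_rows <- rownames(m)[rs == 0]
  dropped_cols <- colnames(m)[cs == 0]
  if (is.null(dropped_rows)) dropped_rows <- which(rs == 0)
  if (is.null(dropped_cols)) dropped_cols <- which(cs == 0)
  m <- m[rs > 0, cs > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("fewer than 2 rows or columns with positive margins")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    dropped_rows = dropped_rows,
    dropped_cols = dropped_cols
  )
}

#' Upper-tail binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, the one-tailed binomial enrichment
#' p-value.
#'
#' @param k observed count of successes.
#' @param n number of trials.
#' @param p0 success probability under the null.
#' @return upper-tail probability.
#' @export
binomial_upper_tail <- function(k, n, p0) {
  if (length(k) != 1L || length(n) != 1L || length(p0) != 1L ||
    anyNA(c(k, n, p0)) || k < 0 || n < 0 || k > n || p0 < 0 || p0 > 1 ||
    k != round(k) || n != round(n)) {
    stop("require 0 <= k <= n and p0 in [0, 1]")
  }
  if (k == 0) {
    return(1)
  }
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Welch two-sample t-test (convenience wrapper)
#'
#' @param x,y numeric vectors.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}
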