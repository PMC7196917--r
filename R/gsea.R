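# Preranked gene-set enrichment from scratch: weighted running-sum
# enrichment score, gene-tag permutation null, normalized enrichment score,
# nominal p with add-one smoothing, and sign-stratified pooled-NES FDR.

# Signed extremum of the running sum for hit positions `pos` (sorted
# ascending, 1-based ranks) with hit weights `w` (same order) in a list of
# length N. The running sum is piecewise linear: it jumps up by w_i/sum(w) at
# each hit and falls by 1/(N - k) per miss, so its extrema occur immediately
# after a hit (peaks) or immediately before one (troughs; the terminal value
# is 0). Returns the signed value of maximal absolute deviation; exact ties
# between the positive and negative extremum resolve to the positive one.
es_from_hits <- function(pos, w, N) {
  k <- length(pos)
  denom <- sum(w)
  if (denom == 0) { # all hit scores zero: fall back to equal weights
    w <- rep(1, k)
    denom <- k
  }
  miss <- 1 / (N - k)
  cw <- cumsum(w) / denom
  after <- cw - (pos - seq_len(k)) * miss
  before <- after - w / denom
  up <- max(after)
  down <- min(before, 0)
  if (up >= abs(down)) up else down
}

#' Weighted running-sum enrichment score
#'
#' At each rank position the running sum gains `|score_i|^w / sum_set
#' |score|^w` on a set member ("hit") and loses `1 / (N - N_hit)` otherwise.
#' The enrichment score is the running-sum value of maximal absolute
#' deviation from zero, signed. The leading edge contains the set members at
#' or before the extremum (at or after it, for a negative score).
#'
#' @param ranked named numeric vector in canonical ranked order (see
#'   [as_ranked_list()]).
#' @param gene_set character vector of member gene ids; members absent from
#'   the ranked list are dropped (the count is reported).
#' @param weight_exponent exponent `w` on `|score|` (default 1, the
#'   "weighted" scoring scheme; 0 gives the classic unweighted statistic).
#' @return list with `es`, `running_sum` (length-N numeric), `leading_edge`,
#'   `n_hits`, `n_dropped`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  N <- length(ranked)
  genes <- names(ranked)
  in_set <- genes %in% gene_set
  k <- sum(in_set)
  n_dropped <- length(unique(gene_set)) - k
  if (k == 0L) stop("gene set has no members in the ranked list")
  if (k == N) stop("gene set covers every ranked gene (degenerate)")
  absw <- abs(ranked)^weight_exponent
  denom <- sum(absw[in_set])
  step <- numeric(N)
  if (denom == 0) {
    step[in_set] <- 1 / k
  } else {
    step[in_set] <- absw[in_set] / denom
  }
  step[!in_set] <- -1 / (N - k)
  rs <- cumsum(step)
  i_max <- which.max(rs)
  i_min <- which.min(rs)
  es <- if (rs[i_max] >= abs(min(rs[i_min], 0))) rs[i_max] else min(rs[i_min], 0)
  if (es >= 0) {
    le <- genes[in_set & seq_len(N) <= i_max]
  } else {
    # the trough precedes the hits that climb back toward zero
    le <- genes[in_set & seq_len(N) > i_min]
  }
  list(
    es = es, running_sum = rs, leading_edge = le,
    n_hits = k, n_dropped = n_dropped
  )
}

#' Gene-tag permutation null for the enrichment score
#'
#' Draws `n_perm` uniformly random gene subsets of the given size from the
#' ranked list and scores each with the weighted running-sum statistic. This
#' is the appropriate null for single-sample preranked input, where sample
#' permutation is impossible.
#'
#' @inheritParams enrichment_score
#' @param set_size subset size per draw.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; the draw is reproducible.
#' @return list with `set_size`, `es` (numeric of length `n_perm`), `seed`.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 10000,
                             weight_exponent = 1, seed = 1L) {
  N <- length(ranked)
  if (set_size < 1L || set_size >= N) {
    stop("set_size must satisfy 1 <= set_size < length(ranked)")
  }
  if (n_perm < 1L) stop("n_perm must be at least 1")
  absw <- abs(ranked)^weight_exponent
  es <- numeric(n_perm)
  rng <- local_rng(seed)
  for (i in seq_len(n_perm)) {
    pos <- sort.int(sample.int(N, set_size))
    es[i] <- es_from_hits(pos, absw[pos], N)
  }
  rng()
  list(set_size = set_size, es = es, seed = seed)
}

# Evaluate RNG state locally: seed on entry, return a restorer to call on
# exit so callers' RNG streams are untouched.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Normalized enrichment score and nominal p-value
#'
#' `NES = ES / mean(|null values with the same sign as ES|)`; the nominal p
#' is the same-sign permutation tail with add-one smoothing,
#' `p = (b + 1) / (m + 1)` with `m` same-sign null draws of which `b` are at
#' least as extreme. When `ES = 0`, or no same-sign null value exists, the
#' NES is reported as 0 with `p = 1`.
#'
#' @param es enrichment score in \[-1, 1\].
#' @param null a null distribution from [permutation_null()].
#' @return list with `nes` and `p_nominal`.
#' @export
nes_and_pvalue <- function(es, null) {
  if (abs(es) > 1 + 1e-12) stop("ES outside [-1, 1]")
  if (length(null$es) == 0L) stop("empty null distribution")
  if (es == 0) {
    return(list(nes = 0, p_nominal = 1))
  }
  same <- if (es > 0) null$es[null$es > 0] else null$es[null$es < 0]
  m <- length(same)
  if (m == 0L) {
    return(list(nes = 0, p_nominal = 1))
  }
  b <- sum(abs(same) >= abs(es))
  list(nes = es / mean(abs(same)), p_nominal = (b + 1) / (m + 1))
}

# Normalize a vector of null ES values by the sign-wise mean absolute value,
# yielding null NES draws for the FDR pool.
normalize_null <- function(es) {
  out <- numeric(length(es))
  pos <- es > 0
  neg <- es < 0
  if (any(pos)) out[pos] <- es[pos] / mean(es[pos])
  if (any(neg)) out[neg] <- es[neg] / mean(abs(es[neg]))
  out
}

#' Preranked GSEA over a collection of gene sets
#'
#' Runs the weighted running-sum statistic with a gene-tag permutation null
#' for every set, and computes FDR q-values by the sign-stratified pooled-NES
#' procedure: observed and permuted enrichment scores are normalized to NES,
#' pooled per sign across sets, and the q-value is the ratio of the null to
#' the observed tail fraction at each observed NES, clipped to \[0, 1\] and
#' monotonized. Results are deterministic for a fixed seed and invariant to
#' the input order of the gene sets.
#'
#' @inheritParams enrichment_score
#' @param gene_sets named list of character vectors.
#' @param n_perm permutations per set (default 10000).
#' @param seed integer seed.
#' @param return_null keep each set's null ES draws in the result (attribute
#'   `null`, a named list) for diagnostics.
#' @return data.frame with one row per set: `set_name`, `size`, `es`, `nes`,
#'   `p_nominal`, `q_fdr`, `leading_edge` (semicolon-joined), `n_dropped`,
#'   `n_perm_used`.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 10000,
                           weight_exponent = 1, seed = 1L,
                           return_null = FALSE) {
  if (length(gene_sets) == 0L) stop("no gene sets supplied")
  if (is.null(names(gene_sets)) || anyDuplicated(names(gene_sets))) {
    stop("gene_sets must have unique names")
  }
  nm_sorted <- sort(names(gene_sets))
  res <- vector("list", length(nm_sorted))
  nulls <- vector("list", length(nm_sorted))
  names(res) <- names(nulls) <- nm_sorted
  for (i in seq_along(nm_sorted)) {
    nm <- nm_sorted[i]
    sc <- enrichment_score(ranked, gene_sets[[nm]], weight_exponent)
    null <- permutation_null(ranked, sc$n_hits, n_perm,
      weight_exponent,
      seed = seed + i
    )
    np <- nes_and_pvalue(sc$es, null)
    res[[nm]] <- data.frame(
      set_name = nm, size = sc$n_hits, es = sc$es, nes = np$nes,
      p_nominal = np$p_nominal,
      leading_edge = paste(sc$leading_edge, collapse = ";"),
      n_dropped = sc$n_dropped, n_perm_used = n_perm,
      stringsAsFactors = FALSE
    )
    nulls[[nm]] <- null$es
  }
  tab <- do.call(rbind, res)
  null_nes <- unlist(lapply(nulls, normalize_null), use.names = FALSE)
  tab$q_fdr <- pooled_nes_fdr(tab$nes, null_nes)
  tab <- tab[match(names(gene_sets), tab$set_name), c(
    "set_name", "size", "es", "nes", "p_nominal", "q_fdr",
    "leading_edge", "n_dropped", "n_perm_used"
  )]
  rownames(tab) <- NULL
  if (return_null) attr(tab, "null") <- nulls
  tab
}

# Sign-stratified pooled-NES FDR: for an observed NES* > 0,
#   q = [#(null NES >= NES*) / #(null NES > 0)] /
#       [#(obs NES >= NES*) / #(obs NES > 0)]
# (mirrored for negative scores), clipped to [0, 1], then monotonized so q
# never decreases as |NES| shrinks within a sign stratum.
pooled_nes_fdr <- function(obs_nes, null_nes) {
  q <- rep(NA_real_, length(obs_nes))
  for (sgn in c(1, -1)) {
    idx <- which(sign(obs_nes) == sgn)
    if (length(idx) == 0L) next
    null_s <- null_nes[sign(null_nes) == sgn]
    obs_s <- obs_nes[idx]
    qs <- vapply(obs_s, function(v) {
      num <- if (length(null_s)) mean(abs(null_s) >= abs(v)) else 0
      den <- mean(abs(obs_s) >= abs(v))
      min(1, num / den)
    }, 1.0)
    # monotonize: weaker |NES| never gets a smaller q
    ord <- order(abs(obs_s), decreasing = TRUE)
    qs[ord] <- cummax(qs[ord])
    q[idx] <- qs
  }
  q[sign(obs_nes) == 0] <- 1
  q
}
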