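# Independent brute-force oracles used to check the implementation paths.
# These deliberately avoid the package's internal algorithms: plain loops,
# exhaustive enumeration, per-base summation.

# Running-sum enrichment score by direct accumulation.
oracle_es <- function(scores, in_set, w = 1) {
  N <- length(scores)
  k <- sum(in_set)
  denom <- sum(abs(scores[in_set])^w)
  rs <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) {
      acc <- acc + if (denom > 0) abs(scores[i])^w / denom else 1 / k
    } else {
      acc <- acc - 1 / (N - k)
    }
    rs[i] <- acc
  }
  up <- max(rs)
  down <- min(rs, 0)
  list(es = if (up >= abs(down)) up else down, running_sum = rs)
}

# Exhaustive gene-tag null: ES of every size-k subset of an N-gene list.
oracle_exhaustive_null <- function(scores, k, w = 1) {
  subs <- utils::combn(length(scores), k)
  apply(subs, 2L, function(idx) {
    in_set <- seq_along(scores) %in% idx
    oracle_es(scores, in_set, w)$es
  })
}

# Two-sided Fisher p by the probability-mass rule over the hypergeometric
# family with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  x <- lo:hi
  pr <- stats::dhyper(x, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (no ties assumed), using the doubled-tail rule capped at 1.
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(vals), n1)
  u_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# All-pairs closest-gene minimizer on 0-based half-open intervals with the
# leftmost-start, then gene-id tie-break.
oracle_closest <- function(peaks, genes) {
  # peaks, genes: data.frames with chrom, start0, end0 (+ gene_id for genes)
  out <- data.frame(
    gene_id = rep(NA_character_, nrow(peaks)),
    distance = rep(NA_real_, nrow(peaks))
  )
  for (i in seq_len(nrow(peaks))) {
    best <- NULL
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      gap <- max(0, genes$start0[j] - peaks$end0[i],
                 peaks$start0[i] - genes$end0[j])
      cand <- list(
        d = gap, start = genes$start0[j],
        id = genes$gene_id[j]
      )
      if (is.null(best) ||
        cand$d < best$d ||
        (cand$d == best$d && cand$start < best$start) ||
        (cand$d == best$d && cand$start == best$start &&
          cand$id < best$id)) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      out$gene_id[i] <- best$id
      out$distance[i] <- best$d
    }
  }
  out
}

# Per-base binned window means around a 0-based midpoint, zero-padded
# outside the covered extent.
oracle_binned_means <- function(track_df, mid0, flank, bin) {
  # track_df: start0, end0, value on one chromosome
  L <- max(track_df$end0)
  base <- numeric(L)
  for (i in seq_len(nrow(track_df))) {
    base[(track_df$start0[i] + 1):track_df$end0[i]] <- track_df$value[i]
  }
  n_bins <- 2 * flank / bin
  vapply(seq_len(n_bins), function(j) {
    s0 <- mid0 - flank + (j - 1) * bin
    pos <- (s0 + 1):(s0 + bin)
    pos <- pos[pos >= 1 & pos <= L]
    sum(base[pos]) / bin
  }, 1.0)
}

# Per-offset log-odds scan of one sequence (forward strand only), with the
# same 1e-4 probability floor as the scanner.
oracle_scan_scores <- function(seq_str, prob, background) {
  lom <- log2(pmax(prob, 1e-4) / background)
  chars <- strsplit(toupper(seq_str), "")[[1]]
  w <- ncol(lom)
  n_off <- length(chars) - w + 1
  vapply(seq_len(n_off), function(o) {
    s <- 0
    for (j in seq_len(w)) {
      ch <- chars[o + j - 1]
      s <- s + if (ch %in% rownames(lom)) lom[ch, j] else -Inf
    }
    s
  }, 1.0)
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# A 12-position HNF1-like position frequency matrix used across tests.
fixture_pwm <- function() {
  counts <- matrix(
    c(
      12, 0, 1, 1,
      0, 0, 0, 14,
      1, 0, 12, 1,
      14, 0, 0, 0,
      14, 0, 0, 0,
      0, 0, 2, 12,
      0, 2, 2, 10,
      0, 0, 0, 14,
      1, 12, 1, 0,
      0, 11, 2, 1,
      14, 0, 0, 0,
      2, 2, 2, 8
    ),
    nrow = 4
  )
  new_pwm("HNF1-like", counts)
}

pwm_consensus <- function(pwm) {
  paste(rownames(pwm$prob)[apply(pwm$prob, 2, which.max)], collapse = "")
}

# Small deterministic expression fixture: genes x samples.
fixture_matrix <- function(n_genes = 20, n_samples = 8, seed = 42) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, 5, 1),
    nrow = n_genes,
    dimnames = list(
      sprintf("g%02d", seq_len(n_genes)),
      sprintf("s%02d", seq_len(n_samples))
    )
  )
  m
}
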