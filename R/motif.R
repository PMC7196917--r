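# Known-motif scanning over region sequences and one-tailed binomial
# enrichment. Scores are log2 odds of the PWM probability (floored at 1e-4)
# against the PWM's background; a hit requires a fixed fraction of the
# maximal attainable score.

# 4 x width log-odds matrix from a pwm object.
pwm_log_odds <- function(pwm, floor = 1e-4) {
  p <- pmax(pwm$prob, floor)
  log2(p / pwm$background)
}

# Score every offset of a single sequence (character string, ACGTN) on the
# forward strand. Positions containing N score -Inf.
scan_one_strand <- function(seq_chars, lom) {
  w <- ncol(lom)
  L <- length(seq_chars)
  n_off <- L - w + 1L
  if (n_off < 1L) {
    return(numeric(0))
  }
  idx <- match(seq_chars, c("A", "C", "G", "T"))
  scores <- numeric(n_off)
  for (j in seq_len(w)) {
    v <- lom[idx[j:(j + n_off - 1L)], j]
    v[is.na(v)] <- -Inf
    scores <- scores + v
  }
  scores
}

#' Scan region sequences for PWM matches
#'
#' Scans both strands of the central `+/- window` bases of each sequence
#' (the full sequence when shorter) and reports log-odds hits at or above
#' `threshold_fraction` of the maximal attainable log-odds score. Sequences
#' shorter than the motif are skipped and flagged; `N` positions never score
#' as hits.
#'
#' @param sequences named character vector or `Biostrings::DNAStringSet` of
#'   region sequences (alphabet ACGTN).
#' @param pwm a `pwm` object (see [read_jaspar()], [new_pwm()]).
#' @param threshold_fraction fraction of the maximal log-odds score required
#'   for a hit (default 0.8, in (0, 1\]).
#' @param window half-width in bases of the scanned central window (default
#'   250).
#' @return list with `hits` (data.frame: `region`, `offset` 0-based within
#'   the full sequence, `strand`, `score`), `region_has_motif` (named
#'   logical over all scanned regions), `skipped` (region ids shorter than
#'   the motif).
#' @export
scan_regions <- function(sequences, pwm, threshold_fraction = 0.8,
                         window = 250) {
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("threshold_fraction must lie in (0, 1]")
  }
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- as.character(seq_along(sequences))
  }
  lom <- pwm_log_odds(pwm)
  w <- pwm$width
  max_score <- sum(apply(lom, 2L, max))
  threshold <- threshold_fraction * max_score
  hits <- list()
  has <- stats::setNames(
    logical(length(sequences)),
    names(sequences)
  )
  skipped <- character(0)
  for (nm in names(sequences)) {
    s <- toupper(sequences[[nm]])
    L <- nchar(s)
    if (L < w) {
      skipped <- c(skipped, nm)
      next
    }
    center <- floor(L / 2)
    from0 <- max(0L, center - as.integer(window))
    to0 <- min(L, center + as.integer(window)) # 0-based half-open window
    sub <- substr(s, from0 + 1L, to0)
    chars <- strsplit(sub, "", fixed = TRUE)[[1L]]
    fwd <- scan_one_strand(chars, lom)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sub))
    )
    rev_scores <- scan_one_strand(strsplit(rc, "", fixed = TRUE)[[1L]], lom)
    sub_len <- length(chars)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") fwd else rev_scores
      hit_idx <- which(sc >= threshold)
      if (length(hit_idx) == 0L) next
      offset0 <- if (strand == "+") {
        from0 + hit_idx - 1L
      } else {
        # offset of the match on the forward coordinates
        from0 + (sub_len - w + 1L - hit_idx)
      }
      hits[[length(hits) + 1L]] <- data.frame(
        region = nm, offset = offset0, strand = strand,
        score = sc[hit_idx], stringsAsFactors = FALSE
      )
      has[[nm]] <- TRUE
    }
  }
  hits <- if (length(hits)) {
    do.call(rbind, hits)
  } else {
    data.frame(
      region = character(0), offset = integer(0),
      strand = character(0), score = numeric(0)
    )
  }
  list(
    hits = hits,
    region_has_motif = has[setdiff(names(sequences), skipped)],
    skipped = skipped
  )
}

#' One-tailed binomial motif enrichment
#'
#' Fraction of regions carrying the motif and the upper-tail binomial
#' p-value of that count against a background hit probability.
#'
#' @param n_with_motif regions with at least one hit.
#' @param n_regions total regions scanned.
#' @param background_prob per-region hit probability under the background.
#' @return list with `fraction`, `p_value`, and `degenerate` (`TRUE` when
#'   `background_prob` is 0 with hits observed, forcing p = 0).
#' @export
motif_region_enrichment <- function(n_with_motif, n_regions,
                                    background_prob) {
  if (n_with_motif < 0 || n_with_motif > n_regions) {
    stop("require 0 <= n_with_motif <= n_regions")
  }
  if (background_prob < 0 || background_prob > 1) {
    stop("background_prob must lie in [0, 1]")
  }
  if (background_prob == 0) {
    return(list(
      fraction = n_with_motif / n_regions,
      p_value = if (n_with_motif > 0) 0 else 1,
      degenerate = n_with_motif > 0
    ))
  }
  list(
    fraction = n_with_motif / n_regions,
    p_value = binomial_upper_tail(n_with_motif, n_regions, background_prob),
    degenerate = FALSE
  )
}

#' Union coverage across motifs
#'
#' Fraction of regions with at least one hit for at least one motif.
#'
#' @param per_motif list of named logical vectors (one per motif) over the
#'   same region ids.
#' @return the union fraction.
#' @export
motif_union_coverage <- function(per_motif) {
  if (length(per_motif) == 0L) stop("no motifs supplied")
  ids <- names(per_motif[[1L]])
  same <- vapply(
    per_motif,
    function(v) identical(sort(names(v)), sort(ids)), TRUE
  )
  if (!all(same)) stop("motifs were scored on different region lists")
  any_hit <- Reduce(`|`, lapply(per_motif, function(v) v[ids]))
  mean(any_hit)
}
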