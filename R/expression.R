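# Expression-matrix operations: probe collapsing, expressed-gene filtering,
# per-sample ranking against the cohort median, and the extreme-decile
# contrast analysis.

#' Canonicalize a ranked gene list
#'
#' Orders a named score vector strictly descending by score, breaking score
#' ties by gene id ascending. This order is the canonical rank order used by
#' the enrichment machinery.
#'
#' @param scores named numeric vector (names are gene ids, unique).
#' @return named numeric vector in canonical ranked order.
#' @export
as_ranked_list <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be named by gene id")
  }
  if (anyDuplicated(names(scores))) stop("duplicate gene ids in ranked list")
  if (any(!is.finite(scores))) stop("ranked scores must be finite")
  scores[order(-scores, names(scores), method = "radix")]
}

#' Collapse probe-level rows to one row per gene
#'
#' For each gene keeps the probe with the highest variance across samples;
#' exact variance ties are broken by the lexicographically smallest probe id.
#' Probes without a gene mapping are dropped.
#'
#' @param probe_matrix numeric matrix, probes x samples, probe rownames.
#' @param mapping data.frame with columns `probe_id`, `gene_id`; each probe
#'   maps to at most one gene.
#' @return numeric matrix with one row per gene (gene rownames).
#' @export
collapse_probes <- function(probe_matrix, mapping) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  if (anyDuplicated(mapping$probe_id)) {
    stop("each probe may map to at most one gene")
  }
  mapping <- mapping[mapping$probe_id %in% rownames(probe_matrix), , drop = FALSE]
  if (nrow(mapping) == 0L) stop("no probe maps to a gene: empty output")
  v <- apply(probe_matrix[mapping$probe_id, , drop = FALSE], 1L, stats::var)
  ord <- order(mapping$gene_id, -v, mapping$probe_id, method = "radix")
  keep <- mapping[ord, , drop = FALSE][!duplicated(mapping$gene_id[ord]), ,
    drop = FALSE
  ]
  out <- probe_matrix[keep$probe_id, , drop = FALSE]
  rownames(out) <- keep$gene_id
  out
}

#' Expressed-gene filter
#'
#' Retains genes with `log2(basemean)` strictly greater than the threshold.
#' Accepts a differential-expression table (with a `basemean` column) or an
#' expression matrix, for which the row mean serves as the basemean proxy.
#'
#' @param x data.frame with columns `gene_id` and `basemean`, or a numeric
#'   matrix with gene rownames.
#' @param threshold log2 basemean cutoff (default 2.5; strict inequality).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(x, threshold = 2.5) {
  if (is.matrix(x)) {
    basemean <- rowMeans(x)
    gene_id <- rownames(x)
  } else {
    basemean <- x$basemean
    gene_id <- x$gene_id
  }
  if (any(basemean < 0)) stop("basemean must be non-negative")
  gene_id[log2(basemean) > threshold]
}

#' Rank one sample's genes against the cohort median
#'
#' Per-gene score `log2((x[g, s] + pc) / (median_over_samples(x[g, ]) + pc))`,
#' returned in canonical descending rank order. This is the per-tumor
#' differential-expression ranking used for single-sample enrichment
#' classification.
#'
#' @param mat expression matrix (genes x samples, linear scale).
#' @param sample_id column to rank.
#' @param pseudocount added to numerator and denominator before the log
#'   (default 1; avoids -Inf at zero counts).
#' @return named numeric vector in ranked order (a ranked list).
#' @export
rank_sample_vs_cohort <- function(mat, sample_id, pseudocount = 1.0) {
  if (!sample_id %in% colnames(mat)) {
    stop("sample not found: ", sample_id)
  }
  if (ncol(mat) < 3L) stop("need at least 3 samples")
  med <- apply(mat, 1L, stats::median)
  score <- log2((mat[, sample_id] + pseudocount) / (med + pseudocount))
  as_ranked_list(stats::setNames(score, rownames(mat)))
}

#' Split samples into extreme deciles
#'
#' Group size is `ceiling(n / 10)`; the high group holds the top-k samples by
#' value and the low group the bottom-k, boundary ties broken by sample id
#' ascending.
#'
#' @param values named numeric vector (names are sample ids).
#' @return list with `low` and `high` character vectors of sample ids.
#' @export
decile_partition <- function(values) {
  n <- length(values)
  if (n < 10L) stop("need at least 10 samples for a decile split")
  if (is.null(names(values))) stop("values must be named by sample id")
  k <- ceiling(n / 10)
  asc <- order(values, names(values), method = "radix")
  desc <- order(-values, names(values), method = "radix")
  list(
    low = names(values)[asc[seq_len(k)]],
    high = names(values)[desc[seq_len(k)]],
    size = k
  )
}

#' Extreme-decile contrast of gene sets
#'
#' Partitions the cohort by a ranking gene's expression into extreme deciles,
#' computes per-gene contrasts
#' `log2((mean over low-decile samples + pc) / (mean over high-decile samples
#' + pc))`, summarizes each gene set (median and IQR of contrasts), tests the
#' sets against each other with Kruskal-Wallis, and reports per-set
#' concordance: the fraction of a set's genes individually significant in the
#' expected direction (two-sided Mann-Whitney per gene at `alpha`).
#'
#' @param mat expression matrix (genes x samples, linear scale).
#' @param ranking_gene gene whose per-sample expression defines the deciles.
#' @param query_sets named list of character vectors (gene sets to test).
#' @param control_set character vector: comparison set.
#' @param pseudocount added before the log ratio (default 1).
#' @param alpha per-gene nominal significance level (default 0.05).
#' @param expected_direction `"down"` (low-decile depletion: contrast < 0) or
#'   `"up"`, per query set (recycled).
#' @return list with `contrasts` (per-gene data.frame), `set_summary`
#'   (median/IQR/concordance per set), `kruskal_p`, and `partition`.
#' @export
decile_contrast <- function(mat, ranking_gene, query_sets, control_set,
                            pseudocount = 1.0, alpha = 0.05,
                            expected_direction = "down") {
  if (!ranking_gene %in% rownames(mat)) {
    stop("ranking gene not in matrix: ", ranking_gene)
  }
  sets <- c(query_sets, list(control = control_set))
  sets <- lapply(sets, intersect, y = rownames(mat))
  if (any(vapply(sets, length, 1L) == 0L)) {
    stop("a gene set has no genes in the matrix")
  }
  expected_direction <- rep_len(expected_direction, length(query_sets))
  part <- decile_partition(mat[ranking_gene, ])
  lo <- mat[, part$low, drop = FALSE]
  hi <- mat[, part$high, drop = FALSE]
  all_genes <- unique(unlist(sets))
  contrast <- log2((rowMeans(lo[all_genes, , drop = FALSE]) + pseudocount) /
    (rowMeans(hi[all_genes, , drop = FALSE]) + pseudocount))
  mw_p <- vapply(all_genes, function(g) {
    suppressWarnings(stats::wilcox.test(lo[g, ], hi[g, ], exact = FALSE)$p.value)
  }, 1.0)
  contrasts <- data.frame(
    gene_id = all_genes, contrast = unname(contrast[all_genes]),
    mw_p = unname(mw_p), row.names = NULL
  )
  summ <- lapply(names(sets), function(nm) {
    cc <- contrast[sets[[nm]]]
    dir <- if (nm %in% names(query_sets)) {
      expected_direction[match(nm, names(query_sets))]
    } else {
      NA_character_
    }
    conc <- if (is.na(dir)) {
      NA_real_
    } else {
      sgn <- if (dir == "down") cc < 0 else cc > 0
      mean(sgn & mw_p[sets[[nm]]] < alpha)
    }
    data.frame(
      set = nm, n_genes = length(cc), median = stats::median(cc),
      iqr_lo = unname(stats::quantile(cc, 0.25)),
      iqr_hi = unname(stats::quantile(cc, 0.75)),
      concordance = conc
    )
  })
  kw <- rank_group_test(lapply(sets, function(g) unname(contrast[g])))
  list(
    contrasts = contrasts,
    set_summary = do.call(rbind, summ),
    kruskal_p = kw$p_value,
    partition = part
  )
}
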