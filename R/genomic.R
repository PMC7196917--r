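# Regulatory-genomics layer on GenomicRanges: promoter/enhancer partition
# around TSSs, closest-gene assignment, binding-vs-DE Fisher enrichment,
# functional-region partition, binned coverage aggregation, and an
# exact-binomial differential-binding surrogate.

#' Closest-gene assignment for peaks
#'
#' Assigns each peak to the gene (or TSS) at minimal interval distance
#' (0 on overlap or adjacency), ignoring strand. Exact distance ties are
#' broken by leftmost gene start, then gene id ascending. Peaks on a
#' chromosome without genes get an `NA` assignment.
#'
#' @param peaks `GRanges` of peaks (metadata `name` used as peak id when
#'   present).
#' @param genes `GRanges` of gene bodies or width-1 TSS points, with a
#'   `gene_id` metadata column.
#' @return data.frame with `peak`, `gene_id`, `distance` (NA when
#'   unassigned), one row per peak in input order.
#' @export
assign_regions_to_genes <- function(peaks, genes) {
  if (length(genes) == 0L) stop("empty gene annotation")
  if (is.null(genes$gene_id)) stop("`genes` needs a gene_id column")
  peak_ids <- if (!is.null(peaks$name)) peaks$name else as.character(seq_along(peaks))
  # candidate nearest genes: any overlap, plus the closest gene on either
  # side (precede/follow with select = "all" keep same-boundary ties, so
  # every distance tie survives into the candidate set)
  cand <- suppressWarnings(rbind(
    as.matrix(GenomicRanges::findOverlaps(peaks, genes,
      ignore.strand = TRUE
    )),
    as.matrix(GenomicRanges::precede(peaks, genes,
      select = "all",
      ignore.strand = TRUE
    )),
    as.matrix(GenomicRanges::follow(peaks, genes,
      select = "all",
      ignore.strand = TRUE
    ))
  ))
  gene_id <- rep(NA_character_, length(peaks))
  dist <- rep(NA_real_, length(peaks))
  if (nrow(cand) > 0L) {
    q <- cand[, 1L]
    s <- cand[, 2L]
    d <- GenomicRanges::distance(peaks[q], genes[s], ignore.strand = TRUE)
    # minimal distance first; ties by leftmost start, then smallest gene id
    ord <- order(q, d, GenomicRanges::start(genes)[s], genes$gene_id[s],
      method = "radix"
    )
    keep <- ord[!duplicated(q[ord])]
    gene_id[q[keep]] <- genes$gene_id[s[keep]]
    dist[q[keep]] <- d[keep]
  }
  data.frame(
    peak = peak_ids, gene_id = gene_id, distance = dist,
    stringsAsFactors = FALSE
  )
}

#' Partition active-chromatin peaks into promoters and enhancers
#'
#' A peak is a promoter when its interval lies within 1 kb of a transcription
#' start site (interval-to-point gap at most `promoter_distance`; 0 means
#' overlap); all remaining peaks are enhancers. Each peak also receives its
#' closest gene by TSS distance.
#'
#' @param active_peaks `GRanges` of active-chromatin peaks.
#' @param tss `GRanges` of width-1 TSS points with a `gene_id` column.
#' @param promoter_distance maximal TSS gap for a promoter call (default
#'   1000 bases).
#' @return `GRanges`: the input peaks with metadata `klass`
#'   (`"promoter"`/`"enhancer"`), `assigned_gene`, `distance`.
#' @export
classify_regulatory_regions <- function(active_peaks, tss,
                                        promoter_distance = 1000) {
  if (length(tss) == 0L) stop("empty TSS annotation")
  if (any(GenomicRanges::width(tss) != 1L)) {
    stop("TSS records must be width-1 points")
  }
  asn <- assign_regions_to_genes(active_peaks, tss)
  out <- active_peaks
  out$klass <- ifelse(!is.na(asn$distance) & asn$distance <= promoter_distance,
    "promoter", "enhancer"
  )
  out$assigned_gene <- asn$gene_id
  out$distance <- asn$distance
  out
}

#' Fisher enrichment of TF binding in a gene class
#'
#' Tabulates bound/unbound against in-class/out-of-class within an
#' expressed-gene background and applies the two-sided Fisher exact test.
#' The odds ratio is `ad/bc` with Haldane 0.5 correction on zero cells.
#'
#' @param bound_genes character vector of TF-bound gene ids.
#' @param class_genes character vector (e.g. downregulated genes); must be a
#'   strict subset of the background.
#' @param background_genes character vector: the expressed-gene universe.
#' @return list with `table` (2x2), `odds_ratio`, `p_value`, `conf_int`,
#'   `haldane`.
#' @export
binding_enrichment <- function(bound_genes, class_genes, background_genes) {
  background_genes <- unique(background_genes)
  if (length(background_genes) == 0L) stop("empty background")
  class_genes <- unique(class_genes)
  if (!all(class_genes %in% background_genes)) {
    stop("class genes must be contained in the background")
  }
  if (setequal(class_genes, background_genes)) {
    stop("class equals background: degenerate column")
  }
  bound <- intersect(unique(bound_genes), background_genes)
  if (length(bound) == 0L) stop("no bound gene in the background")
  in_class <- background_genes %in% class_genes
  is_bound <- background_genes %in% bound
  tab <- matrix(
    c(
      sum(is_bound & in_class), sum(is_bound & !in_class),
      sum(!is_bound & in_class), sum(!is_bound & !in_class)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("bound", "unbound"), c("in_class", "out_of_class"))
  )
  ft <- fisher_exact_2x2(tab)
  c(list(table = tab), ft)
}

#' Partition TF peaks into functional and non-functional binding sites
#'
#' A TF peak is eligible when it overlaps an annotated promoter or enhancer;
#' it is functional when any overlapped region's assigned gene is
#' significantly downregulated (`q < q_threshold` and `log2fc < 0`) in the
#' differential-expression table. The two outputs partition the eligible
#' peaks.
#'
#' @param tf_peaks `GRanges` of TF binding peaks.
#' @param region_classes `GRanges` from [classify_regulatory_regions()].
#' @param de data.frame with columns `gene_id`, `log2fc`, `q`.
#' @param q_threshold FDR cutoff (default 0.05).
#' @return list with `functional` and `non_functional` (`GRanges`) and
#'   `n_ineligible` (peaks overlapping no annotated region).
#' @export
functional_binding_partition <- function(tf_peaks, region_classes, de,
                                         q_threshold = 0.05) {
  ov <- GenomicRanges::findOverlaps(tf_peaks, region_classes,
    ignore.strand = TRUE
  )
  eligible <- unique(S4Vectors::queryHits(ov))
  genes_hit <- region_classes$assigned_gene[S4Vectors::subjectHits(ov)]
  if (!any(genes_hit %in% de$gene_id)) {
    stop("no differential-expression information for any assigned gene")
  }
  de_idx <- match(genes_hit, de$gene_id)
  gene_fun <- !is.na(de_idx) & de$q[de_idx] < q_threshold & de$log2fc[de_idx] < 0
  fun_q <- unique(S4Vectors::queryHits(ov)[gene_fun])
  nonfun_q <- setdiff(eligible, fun_q)
  list(
    functional = tf_peaks[sort(fun_q)],
    non_functional = tf_peaks[sort(nonfun_q)],
    n_ineligible = length(tf_peaks) - length(eligible)
  )
}

# Coverage of a track as a per-chromosome RleList weighted by score.
track_coverage <- function(track) {
  if (is.null(track$score)) stop("track needs a score column")
  GenomicRanges::coverage(track, weight = track$score)
}

#' Binned signal aggregation around region centers
#'
#' Extends a window of `flank` bases either side of each region's midpoint
#' (`floor((start0 + end0) / 2)` in 0-based coordinates), divides it into
#' `bin`-base bins, and reports the mean track value per bin. Bins beyond
#' the covered extent of the chromosome take value 0 and are flagged.
#'
#' @param regions `GRanges`.
#' @param track `GRanges` coverage track with a `score` column (bedGraph
#'   semantics).
#' @param flank half-window in bases; must be a multiple of `bin`.
#' @param bin bin width in bases (default 10).
#' @return list with `matrix` (regions x bins of bin means), `col_means`
#'   (the aggregate profile), `oob` (logical matrix flagging out-of-bounds
#'   bins).
#' @export
aggregate_signal <- function(regions, track, flank, bin = 10) {
  if (bin <= 0) stop("bin must be positive")
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  n_bins <- as.integer(2 * flank / bin)
  cov <- track_coverage(track)
  n <- length(regions)
  mat <- matrix(0, nrow = n, ncol = n_bins)
  oob <- matrix(FALSE, nrow = n, ncol = n_bins)
  start0 <- GenomicRanges::start(regions) - 1L
  end0 <- GenomicRanges::end(regions)
  mid0 <- floor((start0 + end0) / 2)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  offsets <- (seq_len(n_bins) - 1L) * bin
  for (i in seq_len(n)) {
    rle <- if (chroms[i] %in% names(cov)) cov[[chroms[i]]] else S4Vectors::Rle(0, 0L)
    L <- length(rle)
    bs0 <- mid0[i] - flank + offsets # 0-based bin starts
    be0 <- bs0 + bin
    oob[i, ] <- bs0 < 0 | be0 > L
    lo <- pmax(bs0 + 1L, 1L) # 1-based clipped
    hi <- pmin(be0, L)
    ok <- which(lo <= hi)
    if (length(ok) > 0L) {
      v <- IRanges::Views(rle, start = lo[ok], end = hi[ok])
      mat[i, ok] <- IRanges::viewSums(v) / bin
    }
  }
  rownames(mat) <- rownames(oob) <-
    if (!is.null(regions$name)) regions$name else as.character(seq_len(n))
  list(matrix = mat, col_means = colMeans(mat), oob = oob)
}

# Mean track value over each region (zero outside track extent).
region_mean_signal <- function(regions, cov) {
  n <- length(regions)
  out <- numeric(n)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  st <- GenomicRanges::start(regions)
  en <- GenomicRanges::end(regions)
  for (i in seq_len(n)) {
    rle <- if (chroms[i] %in% names(cov)) cov[[chroms[i]]] else S4Vectors::Rle(0, 0L)
    L <- length(rle)
    lo <- max(st[i], 1L)
    hi <- min(en[i], L)
    s <- if (lo <= hi) sum(as.numeric(IRanges::Views(rle, lo, hi)[[1L]])) else 0
    out[i] <- s / (en[i] - st[i] + 1L)
  }
  out
}

#' Per-region log2 fold change between two coverage tracks
#'
#' Mean signal per region in each track, rescaled by total-signal factors
#' that equalize the two track sums, then
#' `log2((mean_a * s_a + pc) / (mean_b * s_b + pc))`. When a two-level
#' `groups` factor is supplied, the fold-change distributions of the two
#' groups are compared with a two-sided Mann-Whitney test.
#'
#' @param regions `GRanges`.
#' @param track_a,track_b `GRanges` coverage tracks with `score` columns.
#' @param pseudocount added to both scaled means (default 0.1).
#' @param groups optional character/factor of length `length(regions)` with
#'   exactly two levels.
#' @return data.frame with `region`, `mean_a`, `mean_b`, `log2fc` (and, when
#'   `groups` is given, attribute `mw_p`, the Mann-Whitney p-value).
#' @export
region_signal_fold_change <- function(regions, track_a, track_b,
                                      pseudocount = 0.1, groups = NULL) {
  tot_a <- sum(as.numeric(GenomicRanges::width(track_a)) * track_a$score)
  tot_b <- sum(as.numeric(GenomicRanges::width(track_b)) * track_b$score)
  if (tot_a <= 0 || tot_b <= 0) stop("zero total signal in a track")
  target <- (tot_a + tot_b) / 2
  s_a <- target / tot_a
  s_b <- target / tot_b
  mean_a <- region_mean_signal(regions, track_coverage(track_a))
  mean_b <- region_mean_signal(regions, track_coverage(track_b))
  fc <- log2((mean_a * s_a + pseudocount) / (mean_b * s_b + pseudocount))
  out <- data.frame(
    region = if (!is.null(regions$name)) {
      regions$name
    } else {
      as.character(seq_along(regions))
    },
    mean_a = mean_a, mean_b = mean_b, log2fc = fc,
    stringsAsFactors = FALSE
  )
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
    sp <- split(fc, groups)
    attr(out, "mw_p") <- suppressWarnings(
      stats::wilcox.test(sp[[1L]], sp[[2L]], exact = FALSE)$p.value
    )
  }
  out
}

#' Exact-binomial differential binding between two conditions
#'
#' A deliberately simple differential-binding statistic: replicate counts
#' are pooled per condition, each region's condition-A fraction is tested
#' against the global (library-size) A-fraction with a two-sided exact
#' binomial test, and p-values are BH-adjusted. Regions with zero total
#' count are excluded and flagged.
#'
#' @param counts_a,counts_b integer matrices (regions x replicates) or
#'   vectors, same regions in the same order.
#' @param fdr significance cutoff on the adjusted p (default 0.05).
#' @return data.frame with `region`, `count_a`, `count_b`, `log2fc`, `p`,
#'   `q`, `significant`, `excluded`.
#' @export
differential_binding <- function(counts_a, counts_b, fdr = 0.05) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b)) stop("region sets differ")
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  if (any(counts_a != round(counts_a)) || any(counts_b != round(counts_b))) {
    stop("counts must be integers")
  }
  a <- rowSums(counts_a)
  b <- rowSums(counts_b)
  lib_a <- sum(a)
  lib_b <- sum(b)
  if (lib_a == 0 || lib_b == 0) stop("a condition has zero total counts")
  p0 <- lib_a / (lib_a + lib_b)
  n <- a + b
  excluded <- n == 0
  p <- rep(NA_real_, length(n))
  idx <- which(!excluded)
  p[idx] <- vapply(idx, function(i) {
    stats::binom.test(a[i], n[i], p0)$p.value
  }, 1.0)
  q <- rep(NA_real_, length(n))
  q[idx] <- bh_adjust(p[idx])
  log2fc <- log2(((a + 0.5) / lib_a) / ((b + 0.5) / lib_b))
  rn <- rownames(counts_a)
  data.frame(
    region = if (!is.null(rn)) rn else as.character(seq_along(n)),
    count_a = a, count_b = b, log2fc = log2fc, p = p, q = q,
    significant = !is.na(q) & q < fdr, excluded = excluded,
    stringsAsFactors = FALSE
  )
}
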