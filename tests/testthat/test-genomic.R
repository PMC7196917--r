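gr <- function(chrom, start0, end0, name = NULL, strand = "*") {
  g <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  if (!is.null(name)) g$name <- name
  g
}

tss_point <- function(chrom, pos0, gene_id, strand = "+") {
  g <- gr(chrom, pos0, pos0 + 1, strand = strand)
  g$gene_id <- gene_id
  g
}

test_that("promoter/enhancer partition by the 1-kb TSS rule", {
  tss <- c(
    tss_point("chrS", 5500, "A"),
    tss_point("chrS", 10000, "B", strand = "-")
  )
  peaks <- c(
    gr("chrS", 5000, 5200, "near"), # gap 300 to A
    gr("chrS", 40000, 40200, "far"),
    gr("chrS", 5400, 5600, "spanning"), # contains the A TSS
    gr("chrS", 6501, 6700, "boundary") # gap 1000: still promoter
  )
  rc <- classify_regulatory_regions(peaks, tss)
  expect_equal(rc$klass, c("promoter", "enhancer", "promoter", "promoter"))
  expect_equal(rc$distance[1], 300)
  expect_equal(rc$distance[3], 0)
  expect_equal(rc$distance[4], 1000)
  expect_equal(rc$assigned_gene, c("A", "B", "A", "A"))
  # the two classes partition the peak set
  expect_setequal(rc$name, peaks$name)
  expect_error(classify_regulatory_regions(peaks, tss[integer(0)]), "empty")
})

test_that("closest-gene assignment matches the all-pairs brute force", {
  genes <- c(
    tss_point("chrS", 1000, "gx"),
    tss_point("chrS", 3000, "ga"),
    gr("chrS", 8000, 9000, strand = "+")
  )
  genes$gene_id[3] <- "gb"
  # peak inside a gene body
  inside <- assign_regions_to_genes(gr("chrS", 8200, 8300, "p"), genes)
  expect_equal(inside$gene_id, "gb")
  expect_equal(inside$distance, 0)

  # exactly equidistant between two genes: leftmost gene start wins
  tie_genes <- c(tss_point("chrS", 1000, "right"), tss_point("chrS", 500, "left"))
  # peak [749, 751): gap 248 to both TSS points... use symmetric midpoint
  tie <- assign_regions_to_genes(gr("chrS", 750, 751, "mid"), tie_genes)
  expect_equal(tie$gene_id, "left")

  # peaks on a chromosome without genes get a null assignment
  orphan <- assign_regions_to_genes(gr("chrX", 100, 200, "o"), genes)
  expect_true(is.na(orphan$gene_id))

  # random instances against the O(n*m) oracle
  set.seed(12)
  for (rep in 1:5) {
    np <- 20
    ng <- 10
    p0 <- sort(sample(0:99900, np))
    g0 <- sort(sample(0:99900, ng))
    peaks <- gr("chrS", p0, p0 + sample(50:400, np, TRUE),
      name = sprintf("p%02d", 1:np)
    )
    genes <- gr("chrS", g0, g0 + sample(200:2000, ng, TRUE))
    genes$gene_id <- sprintf("g%02d", sample(ng))
    got <- assign_regions_to_genes(peaks, genes)
    ref <- oracle_closest(
      data.frame(
        chrom = "chrS", start0 = p0,
        end0 = GenomicRanges::end(peaks)
      ),
      data.frame(
        chrom = "chrS", start0 = g0,
        end0 = GenomicRanges::end(genes), gene_id = genes$gene_id
      )
    )
    expect_equal(got$gene_id, ref$gene_id)
    expect_equal(got$distance, ref$distance)
  }
  expect_error(assign_regions_to_genes(gr("chrS", 1, 2), gr("chrS", 1, 2)[0]), "empty")
})

test_that("binding enrichment builds the 2x2 against the background", {
  bg <- sprintf("g%04d", 1:1000)
  class_g <- bg[1:100] # 100 downregulated
  bound <- c(bg[1:30], bg[101:170]) # 30 in class, 70 outside
  res <- binding_enrichment(bound, class_g, bg)
  expect_equal(unname(res$table), matrix(c(30, 70, 70, 830), 2, byrow = TRUE))
  expect_equal(res$odds_ratio, (30 * 830) / (70 * 70), tolerance = 1e-12)
  expect_error(binding_enrichment(bound, bg, bg), "degenerate")
  expect_error(binding_enrichment(bound, c(class_g, "zz"), bg), "contained")

  # independent random subsets: OR near 1 on average
  set.seed(4)
  ors <- replicate(20, {
    b <- sample(bg, 200)
    cl <- sample(bg, 150)
    binding_enrichment(b, cl, bg)$odds_ratio
  })
  expect_equal(median(ors), 1, tolerance = 0.35)
})

test_that("functional partition separates peaks by their gene's DE status", {
  tss <- c(
    tss_point("chrS", 1000, "A"), tss_point("chrS", 5000, "B"),
    tss_point("chrS", 9000, "C")
  )
  active <- gr("chrS", c(900, 4900, 8900), c(1200, 5200, 9200),
    name = c("r1", "r2", "r3")
  )
  rc <- classify_regulatory_regions(active, tss)
  tf <- gr("chrS", c(950, 4950, 8950), c(1100, 5100, 9100),
    name = c("t1", "t2", "t3")
  )
  de <- data.frame(
    gene_id = c("A", "B", "C"),
    log2fc = c(-2, -1.5, 1.2), q = c(0.001, 0.2, 0.001)
  )
  # A: down & significant; B: not significant; C: up
  fp <- functional_binding_partition(tf, rc, de)
  expect_equal(fp$functional$name, "t1")
  expect_setequal(fp$non_functional$name, c("t2", "t3"))
  expect_equal(fp$n_ineligible, 0)

  # all genes significant & down: everything functional
  de_all <- transform(de, log2fc = -1, q = 0.001)
  expect_length(
    functional_binding_partition(tf, rc, de_all)$non_functional, 0
  )
  # q threshold 0: nothing functional
  expect_length(functional_binding_partition(tf, rc, de, 0)$functional, 0)
  expect_error(
    functional_binding_partition(
      tf, rc,
      data.frame(gene_id = "zz", log2fc = -1, q = 0)
    ),
    "no differential-expression"
  )

  # synthetic landscape: partition equals ground truth exactly
  sim <- gen_regulatory_landscape(
    landscape_sim_config(
      n_genes = 200, genome_length = 2e6,
      n_active_peaks = 160, n_tf_peaks = 80, seed = 6
    ),
    with_tracks = FALSE
  )
  rc2 <- classify_regulatory_regions(
    c(
      GenomicRanges::granges(sim$active_peaks, use.mcols = FALSE),
      GenomicRanges::granges(sim$tf_peaks, use.mcols = FALSE)
    ),
    sim$tss
  )
  rc2$name <- c(sim$active_peaks$name, sim$tf_peaks$name)
  fp2 <- functional_binding_partition(sim$tf_peaks, rc2, sim$de)
  expect_setequal(fp2$functional$name, sim$truth$functional_region_ids)
})

test_that("binned aggregation equals the per-base oracle and conserves signal", {
  # constant track: every matrix entry equals the constant
  const <- gr("chrS", 0, 100000)
  const$score <- 2
  regions <- gr("chrS", c(30000, 60000), c(30400, 60400), c("a", "b"))
  agg <- aggregate_signal(regions, const, flank = 1000, bin = 10)
  expect_equal(dim(agg$matrix), c(2, 200))
  expect_true(all(agg$matrix == 2))
  expect_false(any(agg$oob))

  # column count arithmetic
  agg10k <- aggregate_signal(regions[1], const, flank = 10000, bin = 10)
  expect_equal(ncol(agg10k$matrix), 2000)

  # step-function track vs the per-base summation oracle
  steps0 <- seq(0, 4990, by = 37)
  track_df <- data.frame(
    start0 = steps0,
    end0 = pmin(steps0 + 37, 5000),
    value = round(runif(length(steps0), 0, 5), 3)
  )
  track <- gr("chrS", track_df$start0, track_df$end0)
  track$score <- track_df$value
  reg <- gr("chrS", 2450, 2550, "r") # midpoint 2500
  got <- aggregate_signal(reg, track, flank = 500, bin = 10)
  ref <- oracle_binned_means(track_df, 2500, 500, 10)
  expect_equal(unname(got$matrix[1, ]), ref, tolerance = 1e-9)
  # conservation: total of bin means times bin equals per-base window total
  expect_equal(sum(got$matrix) * 10, sum(ref) * 10, tolerance = 1e-9)

  # out-of-bounds bins are zero-filled and flagged
  edge <- aggregate_signal(gr("chrS", 0, 100, "e"), track,
    flank = 500,
    bin = 10
  )
  expect_true(any(edge$oob))
  expect_true(all(edge$matrix[edge$oob] == 0))
  expect_error(aggregate_signal(reg, track, flank = 500, bin = 0), "positive")
  expect_error(aggregate_signal(reg, track, flank = 505, bin = 10), "multiple")
})

test_that("track fold change is invariant to global scaling", {
  steps0 <- seq(0, 9990, by = 10)
  base <- gr("chrS", steps0, steps0 + 10)
  base$score <- round(runif(length(steps0), 0.5, 3), 3)
  doubled <- base
  doubled$score <- base$score * 2
  regions <- gr("chrS", c(1000, 5000), c(1300, 5300), c("u", "v"))

  same <- region_signal_fold_change(regions, base, base)
  expect_equal(same$log2fc, c(0, 0), tolerance = 1e-9)
  scaled <- region_signal_fold_change(regions, doubled, base)
  expect_equal(scaled$log2fc, c(0, 0), tolerance = 1e-9)

  zero <- base
  zero$score <- 0
  expect_error(region_signal_fold_change(regions, base, zero), "zero total")

  # doubling only at functional regions shows up after normalization
  sim <- gen_regulatory_landscape(
    landscape_sim_config(
      n_genes = 200, genome_length = 2e6,
      n_active_peaks = 160, n_tf_peaks = 80, seed = 9
    )
  )
  fun <- sim$tf_peaks$name %in% sim$truth$functional_region_ids
  fc <- region_signal_fold_change(sim$tf_peaks, sim$track_a, sim$track_b,
    groups = ifelse(fun, "functional", "other")
  )
  expect_equal(
    median(fc$log2fc[fun]) - median(fc$log2fc[!fun]), 1,
    tolerance = 0.25
  )
  expect_lt(attr(fc, "mw_p"), 1e-6)
})

test_that("exact-binomial differential binding", {
  # identical counts: nothing significant
  cts <- matrix(rpois(40, 20), ncol = 2)
  same <- differential_binding(cts, cts)
  expect_false(any(same$significant))

  # one extreme region among balanced ones, equal library sizes
  a <- c(40, rep(20, 30))
  b <- c(0, rep(20, 30))
  # pad the balanced regions so both libraries sum equally
  a <- c(a, 0)
  b <- c(b, 40)
  res <- differential_binding(a, b)
  expect_equal(res$p[1], 2 * 0.5^40, tolerance = 1e-9)
  expect_true(res$significant[1])
  expect_false(any(res$significant[2:31]))

  # swapping conditions negates every log2FC
  swap <- differential_binding(b, a)
  expect_equal(swap$log2fc, -res$log2fc, tolerance = 1e-12)
  expect_equal(swap$p, res$p, tolerance = 1e-12)

  # all-zero regions are excluded with a flag
  withz <- differential_binding(c(0, 10, 5), c(0, 12, 4))
  expect_true(withz$excluded[1])
  expect_true(is.na(withz$p[1]))
  expect_error(differential_binding(c(-1, 2), c(1, 2)), "negative")
})
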