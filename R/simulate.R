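# Synthetic-data generators with known ground truth: an expression cohort
# with a coordinately downregulated gene set, a regulatory landscape of
# TSSs / active peaks / TF peaks / DE outcomes, region sequences with
# planted motif instances, and TMA core scores with a grade effect. Every
# generator is deterministic for a fixed seed.

#' Configuration for the synthetic expression cohort
#'
#' Defaults describe a mid-sized tumor cohort: 120 samples, 2,000 genes, a
#' 100-gene loss-of-function set downshifted by 1 log2 unit in 20% of
#' samples with Gaussian log2 noise (sd 0.5), gene baselines uniform on
#' 3-8 log2 units, mutation penetrance 0.19 in LoF samples against a 0.02
#' background rate (the phenotype/genotype association strength reported
#' for the cohort this emulates).
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param lof_fraction proportion of samples carrying the LoF phenotype.
#' @param set_size size of the downregulated gene set.
#' @param effect_log2 mean downshift (log2 units) of set genes in LoF
#'   samples.
#' @param noise_sd Gaussian noise sd in log2 units.
#' @param baseline_mean_range range of per-gene baseline log2 means.
#' @param mutation_penetrance `P(LoF mutation | LoF sample)`.
#' @param background_mutation_rate `P(LoF mutation | other sample)`.
#' @param seed integer seed.
#' @return a validated config list.
#' @export
cohort_sim_config <- function(n_samples = 120, n_genes = 2000,
                              lof_fraction = 0.2, set_size = 100,
                              effect_log2 = 1.0, noise_sd = 0.5,
                              baseline_mean_range = c(3, 8),
                              mutation_penetrance = 0.19,
                              background_mutation_rate = 0.02,
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    lof_fraction = lof_fraction, set_size = as.integer(set_size),
    effect_log2 = effect_log2, noise_sd = noise_sd,
    baseline_mean_range = baseline_mean_range,
    mutation_penetrance = mutation_penetrance,
    background_mutation_rate = background_mutation_rate,
    seed = as.integer(seed)
  )
  props <- c(
    cfg$lof_fraction, cfg$mutation_penetrance,
    cfg$background_mutation_rate
  )
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$set_size >= cfg$n_genes) stop("set_size must be < n_genes")
  if (cfg$n_samples < 2L) stop("need at least 2 samples")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  cfg
}

#' Generate a synthetic tumor cohort with a downregulated gene set
#'
#' Per-gene baseline log2 means are uniform on `baseline_mean_range`; the
#' log2 value of gene g in sample s is
#' `Normal(baseline_g - effect_log2 * [s is LoF and g in set], noise_sd)`
#' and the matrix holds `2^value` (linear scale, strictly positive).
#' Exactly `round(lof_fraction * n_samples)` samples carry the effect.
#' Mutation labels are drawn per penetrance/background rate; mutated samples
#' receive a putative loss-of-function mutation (a high-impact small variant
#' or a loss-of-function structural variant).
#'
#' @param config from [cohort_sim_config()].
#' @return list with `matrix` (genes x samples, linear scale), `truth`
#'   (lists `lof_sample_ids`, `mutated_sample_ids`, `set_gene_ids`),
#'   `mutations` (data.frame `sample_id`, `mutation_type`, `impact_label`),
#'   `config`.
#' @export
gen_cohort <- function(config = cohort_sim_config()) {
  restore <- local_rng(config$seed)
  on.exit(restore())
  n <- config$n_samples
  g <- config$n_genes
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("G%04d", seq_len(g))
  n_lof <- round(config$lof_fraction * n)
  lof_ids <- sort(sample(sample_ids, n_lof))
  set_genes <- sort(sample(gene_ids, config$set_size))
  baseline <- stats::runif(
    g, config$baseline_mean_range[1L],
    config$baseline_mean_range[2L]
  )
  mu <- matrix(baseline, nrow = g, ncol = n)
  mu[gene_ids %in% set_genes, sample_ids %in% lof_ids] <-
    mu[gene_ids %in% set_genes, sample_ids %in% lof_ids] - config$effect_log2
  log2_vals <- mu + matrix(stats::rnorm(g * n, 0, config$noise_sd),
    nrow = g
  )
  mat <- 2^log2_vals
  dimnames(mat) <- list(gene_ids, sample_ids)
  p_mut <- ifelse(sample_ids %in% lof_ids, config$mutation_penetrance,
    config$background_mutation_rate
  )
  mutated <- stats::runif(n) < p_mut
  types <- c("deletion", "substitution", "insertion", "structural_variant")
  mtype <- rep("none", n)
  mtype[mutated] <- sample(types, sum(mutated), replace = TRUE)
  impact <- ifelse(mtype == "none", "none",
    ifelse(mtype == "structural_variant", "loss_of_function", "high")
  )
  list(
    matrix = mat,
    truth = list(
      lof_sample_ids = lof_ids,
      mutated_sample_ids = sample_ids[mutated],
      set_gene_ids = set_genes
    ),
    mutations = data.frame(
      sample_id = sample_ids, mutation_type = mtype,
      impact_label = impact, stringsAsFactors = FALSE
    ),
    config = config
  )
}

#' Configuration for the synthetic regulatory landscape
#'
#' Defaults: 1,000 genes on a 10-Mb synthetic chromosome, 800 active-
#' chromatin peaks of which half sit at promoters, 400 TF-bound genes, a
#' binding-to-downregulation odds ratio of 5, and 30% of genes
#' downregulated overall.
#'
#' @param n_genes number of genes/TSSs.
#' @param genome_length chromosome length in bases.
#' @param n_active_peaks active-chromatin (H3K27ac-like) peak count.
#' @param n_tf_peaks TF-binding peak count (one bound gene per peak).
#' @param frac_peaks_promoter fraction of active peaks placed within 1 kb of
#'   a TSS.
#' @param binding_down_odds_ratio target odds that a bound gene is
#'   downregulated, relative to unbound genes.
#' @param de_down_fraction overall fraction of downregulated genes.
#' @param chrom synthetic chromosome name.
#' @param seed integer seed.
#' @return a validated config list.
#' @export
landscape_sim_config <- function(n_genes = 1000, genome_length = 1e7,
                                 n_active_peaks = 800, n_tf_peaks = 400,
                                 frac_peaks_promoter = 0.5,
                                 binding_down_odds_ratio = 5,
                                 de_down_fraction = 0.3,
                                 chrom = "chrS", seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    genome_length = as.numeric(genome_length),
    n_active_peaks = as.integer(n_active_peaks),
    n_tf_peaks = as.integer(n_tf_peaks),
    frac_peaks_promoter = frac_peaks_promoter,
    binding_down_odds_ratio = binding_down_odds_ratio,
    de_down_fraction = de_down_fraction,
    chrom = chrom, seed = as.integer(seed)
  )
  if (cfg$binding_down_odds_ratio < 0) stop("odds ratio must be >= 0")
  if (cfg$frac_peaks_promoter < 0 || cfg$frac_peaks_promoter > 1 ||
    cfg$de_down_fraction < 0 || cfg$de_down_fraction > 1) {
    stop("proportions must lie in [0, 1]")
  }
  if (cfg$n_tf_peaks > cfg$n_genes) stop("more TF peaks than genes")
  # each gene needs ~10 kb of room for non-colliding placement
  if (cfg$genome_length < cfg$n_genes * 5000 ||
    cfg$genome_length < (cfg$n_active_peaks + cfg$n_tf_peaks) * 1000) {
    stop("genome too small for the requested features")
  }
  cfg
}

# Solve the unbound downregulation probability p0 so that the bound/unbound
# mixture hits the target overall down fraction at the requested odds ratio.
solve_down_probs <- function(or, frac_bound, down_fraction) {
  p1 <- function(p0) or * p0 / (1 - p0 + or * p0)
  f <- function(p0) frac_bound * p1(p0) + (1 - frac_bound) * p0 - down_fraction
  if (or == 1) {
    return(list(p0 = down_fraction, p1 = down_fraction))
  }
  p0 <- stats::uniroot(f, c(1e-9, 1 - 1e-9))$root
  list(p0 = p0, p1 = p1(p0))
}

#' Generate a synthetic regulatory landscape
#'
#' Places `n_genes` strand-aware TSSs on one synthetic chromosome, active-
#' chromatin peaks at promoters (within 1 kb of a TSS) or distal enhancer
#' positions, and one TF-binding peak near the TSS of each bound gene.
#' Differential-expression outcomes are drawn so that bound genes are
#' downregulated at the configured odds ratio while the overall down
#' fraction matches `de_down_fraction`. Two sparse 10-bp-step coverage
#' tracks are emitted around peak centers; track A doubles (or halves) the
#' signal of track B at functional regions (TF peaks of downregulated
#' bound genes).
#'
#' @param config from [landscape_sim_config()].
#' @param track_direction `"up"` (track A doubled at functional regions) or
#'   `"down"` (halved).
#' @param with_tracks build the coverage tracks (default `TRUE`; disable for
#'   replicate studies that only use intervals and DE outcomes).
#' @return list with `tss`, `active_peaks`, `tf_peaks` (`GRanges`), `de`
#'   (data.frame `gene_id`, `log2fc`, `basemean`, `q`, `direction`),
#'   `track_a`, `track_b` (`GRanges` coverage), `truth` (lists
#'   `bound_gene_ids`, `down_gene_ids`, `functional_region_ids`,
#'   `promoter_peak_ids`), `config`.
#' @export
gen_regulatory_landscape <- function(config = landscape_sim_config(),
                                     track_direction = c("up", "down"),
                                     with_tracks = TRUE) {
  track_direction <- match.arg(track_direction)
  restore <- local_rng(config$seed)
  on.exit(restore())
  chrom <- config$chrom
  g <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(g))
  # TSSs on a regular grid with jitter: guarantees >= 4 kb separation
  slot <- floor(config$genome_length / g)
  tss_pos0 <- (seq_len(g) - 1L) * slot + 2000 +
    sample.int(max(1L, slot - 4000), g, replace = TRUE)
  tss <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = tss_pos0 + 1L, width = 1L),
    strand = sample(c("+", "-"), g, replace = TRUE)
  )
  tss$gene_id <- gene_ids
  tss$name <- gene_ids
  # active peaks: promoter-proximal vs distal placement
  n_act <- config$n_active_peaks
  n_prom <- round(config$frac_peaks_promoter * n_act)
  prom_genes <- sample.int(g, n_prom, replace = n_prom > g)
  peak_w <- 400L
  prom_center0 <- tss_pos0[prom_genes] +
    sample(-800:800, n_prom, replace = TRUE)
  # distal: offset well beyond the promoter window but inside the gene slot
  dist_genes <- sample.int(g, n_act - n_prom, replace = (n_act - n_prom) > g)
  dist_center0 <- tss_pos0[dist_genes] +
    sample(c(-1, 1), n_act - n_prom, TRUE) *
      sample(1500:2000, n_act - n_prom, replace = TRUE)
  centers0 <- pmax(peak_w, c(prom_center0, dist_center0))
  active <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(
      start = centers0 - peak_w %/% 2L + 1L,
      width = peak_w
    )
  )
  active$name <- sprintf("AP%04d", seq_len(n_act))
  active$score <- round(stats::runif(n_act, 10, 1000), 2)
  active <- GenomicRanges::sort(active)
  active$name <- sprintf("AP%04d", seq_len(n_act))
  # TF peaks: one per bound gene, promoter-proximal so closest-gene
  # assignment recovers the intended target
  bound_idx <- sort(sample.int(g, config$n_tf_peaks))
  tf_center0 <- tss_pos0[bound_idx] +
    sample(-600:600, config$n_tf_peaks, replace = TRUE)
  tf <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(start = tf_center0 - 150L + 1L, width = 300L)
  )
  tf$name <- sprintf("TF%04d", seq_len(config$n_tf_peaks))
  tf$score <- round(stats::runif(config$n_tf_peaks, 10, 1000), 2)
  tf$bound_gene <- gene_ids[bound_idx]
  # DE outcomes at the configured binding -> downregulation odds ratio
  pr <- solve_down_probs(
    config$binding_down_odds_ratio,
    config$n_tf_peaks / g, config$de_down_fraction
  )
  bound <- seq_len(g) %in% bound_idx
  down <- stats::runif(g) < ifelse(bound, pr$p1, pr$p0)
  up <- !down & stats::runif(g) < config$de_down_fraction / 2
  log2fc <- numeric(g)
  log2fc[down] <- -abs(stats::rnorm(sum(down), 1, 0.3))
  log2fc[up] <- abs(stats::rnorm(sum(up), 1, 0.3))
  log2fc[!down & !up] <- stats::rnorm(sum(!down & !up), 0, 0.15)
  q <- stats::runif(g, 0.05, 1)
  q[down | up] <- stats::runif(sum(down | up), 0, 0.049)
  de <- data.frame(
    gene_id = gene_ids, log2fc = log2fc,
    basemean = 2^stats::runif(g, 3, 10), q = q,
    direction = ifelse(down, "down", ifelse(up, "up", "ns")),
    stringsAsFactors = FALSE
  )
  functional <- tf$name[tf$bound_gene %in% gene_ids[down]]
  track_a <- track_b <- NULL
  if (with_tracks) {
    tracks <- build_landscape_tracks(
      active, tf, functional, chrom,
      track_direction
    )
    track_a <- tracks$a
    track_b <- tracks$b
  }
  list(
    tss = tss, active_peaks = active, tf_peaks = tf, de = de,
    track_a = track_a, track_b = track_b,
    truth = list(
      bound_gene_ids = gene_ids[bound_idx],
      down_gene_ids = gene_ids[down],
      functional_region_ids = functional,
      promoter_peak_ids = active$name
    ),
    config = config
  )
}

build_landscape_tracks <- function(active, tf, functional, chrom,
                                   track_direction) {
  # sparse coverage in 10-bp steps over +/- 2 kb around every peak center;
  # the A track multiplies the signal of 10-bp bins overlapping functional
  # TF peaks, independent of how nearby peak windows overlap
  all_peaks <- c(GenomicRanges::granges(active), GenomicRanges::granges(tf))
  centers0 <- floor((GenomicRanges::start(all_peaks) - 1 +
    GenomicRanges::end(all_peaks)) / 2)
  windows <- GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(
      start = pmax(1, centers0 - 2000 + 1),
      end = centers0 + 2000
    )
  ))
  # align reduced windows to the 10-bp grid and enumerate bin starts
  w_lo <- (GenomicRanges::start(windows) - 1L) %/% 10L * 10L
  w_hi <- (GenomicRanges::end(windows) + 9L) %/% 10L * 10L
  starts0 <- unlist(mapply(seq, w_lo, w_hi - 10L,
    MoreArgs = list(by = 10L), SIMPLIFY = FALSE
  ))
  bins <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(start = starts0 + 1L, width = 10L)
  )
  fun_peaks <- tf[tf$name %in% functional]
  in_fun <- IRanges::overlapsAny(bins, fun_peaks, ignore.strand = TRUE)
  mult <- if (track_direction == "up") 2 else 0.5
  mk_track <- function(m) {
    val <- 1 + stats::runif(length(bins), 0, 0.2)
    val[in_fun] <- val[in_fun] * m
    tr <- bins
    tr$score <- round(val, 4)
    tr
  }
  list(b = mk_track(1), a = mk_track(mult))
}

#' Generate region sequences with planted motif instances
#'
#' Background bases are drawn i.i.d. from the PWM's background distribution;
#' with probability `insertion_prob` a motif instance (each position sampled
#' from the PWM column distribution) is planted at a uniform offset on a
#' uniform strand.
#'
#' @param n_regions number of regions.
#' @param region_length region length in bases (at least the motif width).
#' @param pwm a `pwm` object.
#' @param insertion_prob planting probability per region.
#' @param seed integer seed.
#' @return list with `sequences` (`Biostrings::DNAStringSet`), `truth`
#'   (list `motif_region_ids`, plus `offsets`, `strands` for planted
#'   regions), `config`.
#' @export
gen_motif_sequences <- function(n_regions, region_length, pwm,
                                insertion_prob, seed = 1L) {
  if (region_length < pwm$width) {
    stop("region_length must be at least the motif width")
  }
  if (insertion_prob < 0 || insertion_prob > 1) {
    stop("insertion_prob must lie in [0, 1]")
  }
  restore <- local_rng(as.integer(seed))
  on.exit(restore())
  bases <- c("A", "C", "G", "T")
  ids <- sprintf("R%04d", seq_len(n_regions))
  planted <- stats::runif(n_regions) < insertion_prob
  offsets <- integer(n_regions)
  strands <- character(n_regions)
  seqs <- vapply(seq_len(n_regions), function(i) {
    s <- sample(bases, region_length, replace = TRUE, prob = pwm$background)
    if (planted[i]) {
      inst <- vapply(seq_len(pwm$width), function(j) {
        sample(bases, 1L, prob = pwm$prob[, j])
      }, "")
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
      }
      off0 <- sample.int(region_length - pwm$width + 1L, 1L) - 1L
      s[(off0 + 1L):(off0 + pwm$width)] <- inst
      offsets[i] <<- off0
      strands[i] <<- strand
    }
    paste(s, collapse = "")
  }, "")
  dss <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  list(
    sequences = dss,
    truth = list(
      motif_region_ids = ids[planted],
      offsets = stats::setNames(offsets[planted], ids[planted]),
      strands = stats::setNames(strands[planted], ids[planted])
    ),
    config = list(
      n_regions = n_regions, region_length = region_length,
      motif_id = pwm$id, insertion_prob = insertion_prob,
      seed = as.integer(seed)
    )
  )
}

#' Generate synthetic TMA core scores with a grade effect
#'
#' Each case receives a latent staining level (`Normal(1.5, 0.8)`, shifted
#' upward by `grade_effect` intensity categories for G3 cases); per-core
#' intensity is the latent level plus core noise, rounded and clamped to
#' 0-3. Percent-positive values scale with intensity. About 2% of cases
#' carry an undetermined grade (`Gx`).
#'
#' @param n_cases number of cases.
#' @param cores_per_case cores per case (at least 1).
#' @param grade_effect latent intensity shift for G3 cases (0 = no grade
#'   association).
#' @param seed integer seed.
#' @param gx_rate fraction of cases with undetermined grade (default 0.02).
#' @return data.frame with `case_id`, `core_id`, `intensity`,
#'   `percent_positive`, `grade`.
#' @export
gen_tma_cases <- function(n_cases, cores_per_case = 2, grade_effect = 0,
                          seed = 1L, gx_rate = 0.02) {
  if (n_cases < 1L) stop("need at least 1 case")
  if (cores_per_case < 1L) stop("need at least 1 core per case")
  restore <- local_rng(as.integer(seed))
  on.exit(restore())
  case_ids <- sprintf("C%03d", seq_len(n_cases))
  grade <- sample(c("G2", "G3"), n_cases, replace = TRUE)
  gx <- stats::runif(n_cases) < gx_rate
  grade[gx] <- "Gx"
  latent <- stats::rnorm(n_cases, 1.5, 0.8) +
    grade_effect * (grade == "G3")
  rows <- lapply(seq_len(n_cases), function(i) {
    intensity <- pmin(3L, pmax(0L, as.integer(round(
      latent[i] + stats::rnorm(cores_per_case, 0, 0.5)
    ))))
    pct <- ifelse(intensity == 0L, 0,
      pmin(100, pmax(1, stats::rnorm(
        cores_per_case,
        25 * intensity, 15
      )))
    )
    data.frame(
      case_id = case_ids[i],
      core_id = sprintf("%s_c%d", case_ids[i], seq_len(cores_per_case)),
      intensity = intensity, percent_positive = round(pct, 1),
      grade = grade[i], stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
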