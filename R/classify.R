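# Sample-level LoF phenotype classification: single-sample preranked GSEA
# against a loss-of-function gene set, three-way labeling by NES sign and
# nominal p, mutation-status association, and cross-class expression
# comparison.

#' Classify one sample from its ranked list
#'
#' Runs preranked enrichment of the LoF gene set on the sample's ranked list
#' and applies the three-way rule: `LoF` when `NES < 0` and `p < alpha`
#' (coordinated downregulation of the set), `Control1` when `NES < 0` and
#' `p >= alpha`, and `Control2` when `NES >= 0` (a zero or undefined NES
#' falls in `Control2`; `p` exactly at `alpha` falls in `Control1`).
#'
#' @param ranked named numeric vector in canonical ranked order.
#' @param lof_set character vector: loss-of-function gene set.
#' @param n_perm permutations for the null (default 1000).
#' @param alpha nominal significance level (default 0.05).
#' @param seed integer seed.
#' @return list with `label` (one of `"LoF"`, `"Control1"`, `"Control2"`),
#'   `nes`, `p_nominal`, `es`.
#' @export
classify_sample <- function(ranked, lof_set, n_perm = 1000, alpha = 0.05,
                            seed = 1L) {
  sc <- enrichment_score(ranked, lof_set)
  null <- permutation_null(ranked, sc$n_hits, n_perm, seed = seed)
  np <- nes_and_pvalue(sc$es, null)
  label <- if (np$nes < 0) {
    if (np$p_nominal < alpha) "LoF" else "Control1"
  } else {
    "Control2"
  }
  list(label = label, nes = np$nes, p_nominal = np$p_nominal, es = sc$es)
}

#' Classify every sample of a cohort
#'
#' For each sample, ranks its genes against the cohort median profile
#' ([rank_sample_vs_cohort()]) and classifies it with [classify_sample()].
#' The three labels partition the cohort. Per-sample permutation seeds are
#' derived from the sample id's rank among sorted ids, so the classification
#' is invariant to column order.
#'
#' @param mat expression matrix (genes x samples, linear scale).
#' @param lof_set character vector: loss-of-function gene set.
#' @param n_perm permutations per sample (default 1000).
#' @param alpha nominal significance level (default 0.05).
#' @param seed integer base seed.
#' @param pseudocount pseudocount for the log-ratio ranking (default 1).
#' @return data.frame with columns `sample_id`, `label`, `nes`, `p_nominal`.
#' @export
classify_cohort <- function(mat, lof_set, n_perm = 1000, alpha = 0.05,
                            seed = 1L, pseudocount = 1.0) {
  if (ncol(mat) < 3L) stop("need at least 3 samples")
  ids <- colnames(mat)
  id_rank <- match(ids, sort(ids))
  rows <- lapply(seq_along(ids), function(i) {
    ranked <- rank_sample_vs_cohort(mat, ids[i], pseudocount)
    cl <- classify_sample(ranked, lof_set, n_perm, alpha,
      seed = seed + id_rank[i]
    )
    data.frame(
      sample_id = ids[i], label = cl$label, nes = cl$nes,
      p_nominal = cl$p_nominal, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify mutation records by functional impact
#'
#' A mutation is a putative loss-of-function (`LoF_mutant`) if it is a small
#' variant (deletion, substitution, insertion) annotated with high functional
#' impact, or a structural variant annotated as loss-of-function. Mutations
#' of unknown consequence are labeled `unknown`; unmutated samples are
#' `wildtype`.
#'
#' @param mutation_type character vector over `deletion`, `substitution`,
#'   `insertion`, `structural_variant`, `none`.
#' @param impact_label character vector over `high`, `loss_of_function`,
#'   `unknown`, `none`.
#' @return character vector over `LoF_mutant`, `unknown`, `wildtype`.
#' @export
classify_mutation_record <- function(mutation_type, impact_label) {
  ok_type <- c(
    "deletion", "substitution", "insertion",
    "structural_variant", "none"
  )
  ok_imp <- c("high", "loss_of_function", "unknown", "none")
  if (!all(mutation_type %in% ok_type)) {
    stop(
      "unrecognized mutation type: ",
      paste(setdiff(mutation_type, ok_type), collapse = ", ")
    )
  }
  if (!all(impact_label %in% ok_imp)) {
    stop(
      "unrecognized impact label: ",
      paste(setdiff(impact_label, ok_imp), collapse = ", ")
    )
  }
  small <- mutation_type %in% c("deletion", "substitution", "insertion")
  lof <- (small & impact_label == "high") |
    (mutation_type == "structural_variant" & impact_label == "loss_of_function")
  out <- ifelse(lof, "LoF_mutant",
    ifelse(mutation_type != "none" & impact_label == "unknown",
      "unknown", "wildtype"
    )
  )
  out
}

#' Association between LoF phenotype and LoF mutation status
#'
#' Builds the 2x2 table of phenotype class (`LoF` vs all other classes)
#' against mutation status (`LoF_mutant` vs not; unknown-consequence
#' mutations count as not) and tests it with the two-sided Fisher exact test.
#'
#' @param classes data.frame from [classify_cohort()] (columns `sample_id`,
#'   `label`).
#' @param mutations data.frame with columns `sample_id`, `mutation_type`,
#'   `impact_label`.
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p_value`,
#'   `conf_int`.
#' @export
mutation_association <- function(classes, mutations) {
  common <- intersect(classes$sample_id, mutations$sample_id)
  if (length(common) == 0L) stop("no shared sample ids")
  cl <- classes[match(common, classes$sample_id), ]
  mu <- mutations[match(common, mutations$sample_id), ]
  status <- classify_mutation_record(mu$mutation_type, mu$impact_label)
  is_lof_class <- cl$label == "LoF"
  is_mut <- status == "LoF_mutant"
  tab <- matrix(
    c(
      sum(is_lof_class & is_mut), sum(is_lof_class & !is_mut),
      sum(!is_lof_class & is_mut), sum(!is_lof_class & !is_mut)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      c("LoF_class", "other_class"),
      c("LoF_mutant", "not_mutant")
    )
  )
  ft <- fisher_exact_2x2(tab)
  list(
    table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value,
    conf_int = ft$conf_int
  )
}

#' Compare one gene's expression across phenotype classes
#'
#' @param mat expression matrix.
#' @param gene_id gene to compare.
#' @param classes data.frame with `sample_id` and `label`.
#' @return list with `groups` (named list of values), `summary` (median/IQR
#'   per class), `statistic`, `p_value` (Kruskal-Wallis; for two classes the
#'   Mann-Whitney p is also reported as `mann_whitney_p`).
#' @export
group_expression_compare <- function(mat, gene_id, classes) {
  if (!gene_id %in% rownames(mat)) stop("gene not in matrix: ", gene_id)
  classes <- classes[classes$sample_id %in% colnames(mat), ]
  split_ids <- split(classes$sample_id, classes$label)
  split_ids <- split_ids[vapply(split_ids, length, 1L) > 0L]
  if (length(split_ids) < 2L) stop("need at least 2 non-empty classes")
  groups <- lapply(split_ids, function(s) unname(mat[gene_id, s]))
  rt <- rank_group_test(groups)
  summ <- do.call(rbind, lapply(names(groups), function(nm) {
    v <- groups[[nm]]
    data.frame(
      label = nm, n = length(v), median = stats::median(v),
      iqr_lo = unname(stats::quantile(v, 0.25)),
      iqr_hi = unname(stats::quantile(v, 0.75))
    )
  }))
  list(
    groups = groups, summary = summ, statistic = rt$statistic,
    p_value = rt$p_value, mann_whitney_p = rt$mann_whitney_p
  )
}
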