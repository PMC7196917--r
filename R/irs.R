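# Immunoreactive score (Remmele-Stegner) for tissue-microarray cores:
# per-core IRS = intensity category (0-3) x percent-positive category (0-4),
# case-level mean aggregation, four-group classification, and grade
# association by chi-square.

#' Percent-positive category of a stained core
#'
#' Bins: no staining (< 1%) = 0, 1-9% = 1, 10-50% = 2, 50-80% = 3,
#' > 80% = 4. The published bins overlap at exactly 50%, which is assigned
#' to the lower bin (category 2).
#'
#' @param percent_positive percentage of positive cells in \[0, 100\]
#'   (vectorized).
#' @return integer category 0-4.
#' @export
proportion_score <- function(percent_positive) {
  if (anyNA(percent_positive) ||
    any(percent_positive < 0 | percent_positive > 100)) {
    stop("percent_positive must lie in [0, 100]")
  }
  out <- integer(length(percent_positive))
  out[percent_positive >= 1] <- 1L
  out[percent_positive >= 10] <- 2L
  out[percent_positive > 50] <- 3L
  out[percent_positive > 80] <- 4L
  out
}

# Group bins on the (possibly non-integer) mean IRS: continuous extension of
# the published integer bins 0-1 / 2-3 / 4-8 / 9-12.
irs_group <- function(irs) {
  if (any(irs < 0 | irs > 12)) stop("IRS must lie in [0, 12]")
  labels <- c("negative", "weak", "moderate", "strong")
  grp <- findInterval(irs, c(0, 2, 4, 9)) # 1..4
  factor(labels[grp], levels = labels)
}

#' Immunoreactive score of a single core
#'
#' `IRS = intensity x proportion category`, a score from 0 to 12, grouped as
#' 0-1 negative (group 0), 2-3 weak (1), 4-8 moderate (2), 9-12 strong (3).
#'
#' @param intensity staining intensity category 0-3 (vectorized).
#' @param proportion_score percent-positive category 0-4 (vectorized).
#' @return data.frame with `irs` (0-12), `group` (factor), `group_code`
#'   (0-3).
#' @export
compute_irs <- function(intensity, proportion_score) {
  if (any(!intensity %in% 0:3)) stop("intensity must be in 0..3")
  if (any(!proportion_score %in% 0:4)) {
    stop("proportion score must be in 0..4")
  }
  irs <- intensity * proportion_score
  grp <- irs_group(irs)
  data.frame(irs = irs, group = grp, group_code = as.integer(grp) - 1L)
}

#' Aggregate core scores to one IRS per case
#'
#' When a case has several tumor cores, the mean of their per-core IRS values
#' is taken; the group is assigned from the mean using the continuous
#' extension of the published bins (\[0,2) negative, \[2,4) weak, \[4,9)
#' moderate, \[9,12\] strong).
#'
#' @param cores data.frame with columns `case_id`, `intensity`,
#'   `percent_positive`, and optionally `grade` (constant within a case).
#' @return data.frame with one row per case: `case_id`, `n_cores`,
#'   `mean_irs`, `group`, `group_code` (and `grade` when supplied).
#' @export
case_aggregate <- function(cores) {
  if (nrow(cores) == 0L) stop("no cores supplied")
  per_core <- compute_irs(cores$intensity, proportion_score(cores$percent_positive))
  agg <- stats::aggregate(per_core$irs, list(case_id = cores$case_id), mean)
  names(agg)[2L] <- "mean_irs"
  agg$n_cores <- as.integer(table(cores$case_id)[agg$case_id])
  agg$group <- irs_group(agg$mean_irs)
  agg$group_code <- as.integer(agg$group) - 1L
  if (!is.null(cores$grade)) {
    gr <- tapply(as.character(cores$grade), cores$case_id, function(g) {
      u <- unique(g)
      if (length(u) > 1L) stop("grade differs between cores of one case")
      u
    })
    agg$grade <- as.character(gr[agg$case_id])
  }
  agg[order(agg$case_id), c(
    "case_id", "n_cores", "mean_irs", "group", "group_code",
    intersect("grade", names(agg))
  )]
}

#' Association between IRS group and tumor grade
#'
#' Cases with undetermined grade (`Gx`) are omitted; the G2/G3-by-group
#' contingency table is tested with the Pearson chi-square statistic
#' (no continuity correction). Groups without any case drop out of the
#' table (flagged by [chi_square_independence()]).
#'
#' @param cases data.frame from [case_aggregate()] with `group` and `grade`
#'   columns.
#' @return list with `table` (grades x groups), `statistic`, `df`,
#'   `p_value`, `n_excluded` (Gx cases removed), `dropped_cols`.
#' @export
grade_association <- function(cases) {
  if (is.null(cases$grade)) stop("cases need a grade column")
  keep <- cases$grade != "Gx"
  n_excluded <- sum(!keep)
  cases <- cases[keep, ]
  if (length(unique(cases$grade)) < 2L) {
    stop("fewer than 2 grades after Gx exclusion")
  }
  tab <- table(grade = cases$grade, group = cases$group)
  ct <- chi_square_independence(tab)
  list(
    table = tab, statistic = ct$statistic, df = ct$df,
    p_value = ct$p_value, n_excluded = n_excluded,
    dropped_cols = ct$dropped_cols
  )
}
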