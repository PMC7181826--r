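#' Per-site R-loop induction score
#'
#' Reduces a break-centered fold-change profile to a single number: the
#' arithmetic mean of the per-nucleotide log2 fold change over the 1-kb
#' region centered on the break (relative positions `-score_half_width ..
#' +score_half_width`, 1001 values at the default).
#'
#' @param profile A `fold_change_profile`.
#' @param score_half_width Half-width of the scoring region, default 500.
#' @return The mean log2 fold change (a length-1 numeric).
#' @export
induction_score <- function(profile, score_half_width = 500L) {
  stopifnot(inherits(profile, "fold_change_profile"))
  if (score_half_width > profile$half_width) {
    stop("score_half_width (", score_half_width,
         ") exceeds the profile half-width (", profile$half_width, ")")
  }
  center <- profile$half_width + 1L
  idx <- (center - score_half_width):(center + score_half_width)
  mean(profile$lfc[idx])
}

#' Split anchor sites into high- and low-activity classes
#'
#' The grouped comparison of damage-induced R-loop formation needs a
#' binary transcriptional-activity class.  `median_split` (default) labels
#' sites with activity strictly above the median as `high`; `threshold`
#' uses a supplied cutoff instead, so a published classification can be
#' reproduced directly.
#'
#' @param sites An `anchor_sites` table (or any data frame with an
#'   `activity` column).
#' @param mode `"median_split"` or `"threshold"`.
#' @param threshold Cutoff for `threshold` mode; activity strictly above
#'   it is `high`.
#' @return A factor of `"high"` / `"low"`, one per site.
#' @export
classify_activity <- function(sites, mode = c("median_split", "threshold"),
                              threshold = NULL) {
  mode <- match.arg(mode)
  a <- sites$activity
  if (mode == "median_split") {
    if (length(a) < 2L) stop("median_split needs at least 2 sites")
    cut <- stats::median(a)
    if (all(a == a[1L])) {
      warning("all activities equal; median split labels every site low")
    }
  } else {
    if (is.null(threshold)) stop("threshold mode requires a threshold")
    cut <- threshold
  }
  factor(ifelse(a > cut, "high", "low"), levels = c("high", "low"))
}

#' Unpaired Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks are used for ties.  The p value is exact (by enumeration of
#' rank assignments) when the two groups together hold at most 12
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction is used.  `alternative = "greater"`
#' tests whether `x` is stochastically larger than `y`.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exact_max Largest combined sample size for which the exact
#'   branch is taken (default 12).
#' @return A list with `statistic` (the Mann-Whitney U for `x`), `p_raw`,
#'   `alternative`, `n_x`, `n_y` and `exact` (logical).
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two.sided", "greater", "less"),
                          exact_max = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= exact_max) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p_raw = wt$p.value,
       alternative = alternative, n_x = length(x), n_y = length(y),
       exact = exact)
}

#' Pearson correlation with t-test
#'
#' Sample Pearson coefficient with the standard two-sided test
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("Pearson test needs n >= 3")
  if (stats::sd(x) == 0) stop("x has zero variance")
  if (stats::sd(y) == 0) stop("y has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bonferroni adjustment
#'
#' Each p value is multiplied by the family size and capped at 1.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param m Family size; defaults to `length(p_values)`.
#' @return Adjusted p values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  pmin(1, p_values * m)
}

#' Build the per-site induction score table
#'
#' Joins induction scores with the anchor-site metadata and the binary
#' activity class used by the grouped comparisons.
#'
#' @param profiles A list of `fold_change_profile` objects, one per site.
#' @param sites The matching `anchor_sites` table.
#' @param score_half_width Passed to [induction_score()].
#' @param split_mode,split_threshold Passed to [classify_activity()].
#' @return A `site_scores` data frame with columns `site_id`, `score`,
#'   `activity`, `pathway`, `genic`, `activity_class`.
#' @export
score_sites <- function(profiles, sites, score_half_width = 500L,
                        split_mode = "median_split",
                        split_threshold = NULL) {
  ids <- vapply(profiles, `[[`, character(1), "site_id")
  missing <- setdiff(sites$site_id, ids)
  extra <- setdiff(ids, sites$site_id)
  if (length(missing) || length(extra)) {
    stop("site/profile mismatch; missing profiles: ",
         paste(missing, collapse = ", "), "; orphan profiles: ",
         paste(extra, collapse = ", "))
  }
  profiles <- profiles[match(sites$site_id, ids)]
  scores <- vapply(profiles, induction_score, numeric(1),
                   score_half_width = score_half_width)
  structure(
    data.frame(site_id = sites$site_id, score = scores,
               activity = sites$activity, pathway = sites$pathway,
               genic = sites$genic,
               activity_class = classify_activity(sites, split_mode,
                                                  split_threshold),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("site_scores", "data.frame"))
}

#' Grouped comparisons of induction scores
#'
#' Runs the three comparisons of the break-centered analysis on a score
#' table: repair pathway (HR vs NHEJ), genic status (intragenic vs
#' intergenic) and transcriptional activity (high vs low), each an
#' unpaired Wilcoxon rank-sum test, Bonferroni-corrected over the
#' comparisons actually run.  Defaults test activity one-sided
#' (`high > low`, the transcription-dependence hypothesis) and the other
#' two two-sided.
#'
#' @param scores A `site_scores` table.
#' @param alternatives Named list of alternatives per comparison.
#' @return A `data.frame` with one row per executed comparison:
#'   `comparison`, `group_a`, `group_b`, `n_a`, `n_b`, `statistic`,
#'   `alternative`, `p_raw`, `p_adjusted`.
#' @export
run_comparisons <- function(scores,
                            alternatives = list(activity = "greater",
                                                pathway = "two.sided",
                                                genic = "two.sided")) {
  stopifnot(is.data.frame(scores))
  plan <- list(
    activity = list(var = "activity_class", a = "high", b = "low"),
    pathway = list(var = "pathway", a = "HR", b = "NHEJ"),
    genic = list(var = "genic", a = "intragenic", b = "intergenic"))
  rows <- list()
  for (name in names(plan)) {
    p <- plan[[name]]
    xa <- scores$score[scores[[p$var]] == p$a]
    xb <- scores$score[scores[[p$var]] == p$b]
    if (length(xa) == 0L || length(xb) == 0L) {
      warning("comparison ", name, " skipped: empty group (",
              p$a, ": n=", length(xa), ", ", p$b, ": n=", length(xb), ")")
      next
    }
    alt <- alternatives[[name]] %||% "two.sided"
    rs <- rank_sum_test(xa, xb, alternative = alt)
    rows[[name]] <- data.frame(
      comparison = name, group_a = p$a, group_b = p$b,
      n_a = rs$n_x, n_b = rs$n_y, statistic = rs$statistic,
      alternative = alt, p_raw = rs$p_raw, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(comparison = character(), group_a = character(),
                      group_b = character(), n_a = integer(),
                      n_b = integer(), statistic = numeric(),
                      alternative = character(), p_raw = numeric(),
                      p_adjusted = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- bonferroni(out$p_raw, m = nrow(out))
  out
}

#' Correlate induction scores with transcriptional activity
#'
#' @param scores A `site_scores` table.
#' @return A list with the [pearson_test()] result plus the fitted
#'   least-squares line (`intercept`, `slope`) for scatter plots.
#' @export
correlate_activity <- function(scores) {
  ct <- pearson_test(scores$activity, scores$score)
  fit <- stats::lm(score ~ activity, data = scores)
  c(ct, list(intercept = unname(stats::coef(fit)[1L]),
             slope = unname(stats::coef(fit)[2L])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
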