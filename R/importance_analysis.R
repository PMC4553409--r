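#' Rank-based feature importance over cross-validation runs
#'
#' Within each run the selected features receive linearly decreasing raw
#' scores (the top feature gets m, the number of features selected in that
#' run; the last gets 1), normalized so each run contributes total mass 1.
#' Feature- and sub-category-level importance is the sum of the relevant
#' normalized scores over runs; the total mass therefore always equals the
#' number of runs.
#'
#' @name importance_analysis
NULL

#' Normalized rank scores for one run
#'
#' @param selected ordered feature names, most important first (nonempty,
#'   unique).
#' @return Named numeric vector: rank j of m gets `(m - j + 1) / (m (m + 1) / 2)`;
#'   the scores are strictly decreasing and sum to 1. A run selecting a single
#'   feature gives that feature score 1.
#' @export
run_scores <- function(selected) {
  if (!length(selected)) stop("a run must select at least one feature")
  if (anyDuplicated(selected)) stop("duplicate feature names in one run")
  m <- length(selected)
  stats::setNames((m:1) / (m * (m + 1) / 2), selected)
}

#' Aggregate run scores into an importance report
#'
#' @param runs list of per-run normalized score vectors (from [run_scores()]).
#' @param subcategory named character vector mapping every scored feature to
#'   its sub-category.
#' @return An object of class `importance_report`: per-feature total scores
#'   (descending), per-sub-category scores and percentages (of the total mass,
#'   which equals the number of runs), and `n_runs`.
#' @export
aggregate_importance <- function(runs, subcategory) {
  stopifnot(length(runs) >= 1)
  all_scores <- unlist(runs)
  feats <- names(all_scores)
  unknown <- setdiff(unique(feats), names(subcategory))
  if (length(unknown))
    stop("features without a sub-category tag: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  feature_scores <- tapply(all_scores, feats, sum)
  feature_scores <- sort(unclass(feature_scores), decreasing = TRUE)
  tags <- unname(subcategory[names(feature_scores)])
  subcat_scores <- vapply(FEATURE_SUBCATEGORIES,
                          function(s) sum(feature_scores[tags == s]),
                          numeric(1))
  n_runs <- length(runs)
  structure(list(feature_scores = feature_scores,
                 feature_subcategory = stats::setNames(tags, names(feature_scores)),
                 subcategory_scores = subcat_scores,
                 subcategory_percent = 100 * subcat_scores / n_runs,
                 n_runs = n_runs),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> %d runs, %d scored features (total mass %.6f)\n",
              x$n_runs, length(x$feature_scores), sum(x$feature_scores)))
  pc <- x$subcategory_percent
  cat("  sub-category share:",
      paste(sprintf("%s %.1f%%", names(pc), pc), collapse = ", "), "\n")
  top <- utils::head(x$feature_scores, 5)
  for (i in seq_along(top))
    cat(sprintf("  %d. %s (%s): %.4f\n", i, names(top)[i],
                x$feature_subcategory[names(top)[i]], top[i]))
  invisible(x)
}

#' Importance report from a cross-validation result
#'
#' @param result a [loocv()] result.
#' @param table the [feature_table()] the result was computed on (supplies
#'   the sub-category tags).
#' @return An `importance_report` over the per-fold selected feature sets.
#' @export
importance_from_loocv <- function(result, table) {
  stopifnot(inherits(result, "loocv_result"), inherits(table, "feature_table"))
  runs <- lapply(result$folds, function(f) run_scores(f$selection$selected))
  aggregate_importance(runs, table$subcategory)
}
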