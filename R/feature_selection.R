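#' Random-forest feature selection
#'
#' The selection procedure run inside every cross-validation fold: Gini
#' importance of each feature averaged over repeated forests per sub-category,
#' the top features of each sub-category pooled and re-ranked, then forests
#' grown on growing prefixes of the pooled ranking; the shortest prefix
#' attaining the minimum out-of-bag error is the selected feature set.
#'
#' @name feature_selection
NULL

FEATURE_SUBCATEGORIES <- c("ALFF", "fALFF", "ReHo", "FC", "NMglobal", "NMnodal")

#' Feature table
#'
#' Subjects x features matrix with per-feature sub-category tags and
#' per-subject laterality labels.
#'
#' @param values numeric matrix, subjects in rows, uniquely named feature
#'   columns.
#' @param subcategory character vector (one of ALFF, fALFF, ReHo, FC,
#'   NMglobal, NMnodal per feature).
#' @param labels per-subject labels, `"L"` or `"R"`.
#' @param subject_ids optional subject identifiers.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, subcategory, labels, subject_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("feature columns must carry unique names")
  if (length(subcategory) != ncol(values))
    stop("one sub-category tag per feature required")
  if (!all(subcategory %in% FEATURE_SUBCATEGORIES))
    stop("unknown sub-category tag(s): ",
         paste(setdiff(subcategory, FEATURE_SUBCATEGORIES), collapse = ", "))
  if (length(labels) != nrow(values) || !all(labels %in% c("L", "R")))
    stop("labels must be one 'L'/'R' value per subject")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%02d", seq_len(nrow(values)))
  structure(list(values = values,
                 subcategory = stats::setNames(subcategory, colnames(values)),
                 labels = labels, subject_ids = subject_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(factor(x$subcategory, levels = FEATURE_SUBCATEGORIES))
  cat(sprintf("<feature_table> %d subjects (%d L / %d R), %d features\n",
              nrow(x$values), sum(x$labels == "L"), sum(x$labels == "R"),
              ncol(x$values)))
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

subset_features <- function(table, feature_names) {
  feature_table(table$values[, feature_names, drop = FALSE],
                unname(table$subcategory[feature_names]),
                table$labels, table$subject_ids)
}

subset_subjects <- function(table, idx) {
  feature_table(table$values[idx, , drop = FALSE],
                unname(table$subcategory),
                table$labels[idx], table$subject_ids[idx])
}

fit_forest <- function(X, y, n_trees, seed, importance = "none") {
  ranger::ranger(x = X, y = factor(y, levels = c("L", "R")),
                 num.trees = n_trees, importance = importance,
                 num.threads = 1, seed = seed)
}

#' Gini importance from one random forest
#'
#' Trains a classification forest and returns each feature's total decrease
#' in Gini impurity summed over all splits of all trees. Defaults follow
#' common practice at small n: 500 trees, sqrt(F) candidate features per
#' split, bootstrap sampling with replacement.
#'
#' @param X subjects x features numeric matrix (named columns).
#' @param y class labels (`"L"`/`"R"`), at least 2 subjects per class.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return Named nonnegative numeric vector of importances.
#' @export
rf_gini_importance <- function(X, y, n_trees = 500, seed = 1L) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 2) stop("need at least 2 subjects per class")
  fit <- fit_forest(X, y, n_trees, seed, importance = "impurity")
  imp <- fit$variable.importance
  imp[imp < 0] <- 0
  imp
}

mean_importance <- function(X, y, n_reps, n_trees, seed) {
  total <- numeric(ncol(X))
  for (r in seq_len(n_reps))
    total <- total + rf_gini_importance(X, y, n_trees, seed = seed + r)
  stats::setNames(total / n_reps, colnames(X))
}

# Deterministic importance ordering: descending mean importance, feature name
# breaking exact ties.
order_by_importance <- function(imp) {
  names(imp)[order(-imp, names(imp))]
}

# Column standard deviations without per-column R calls.
col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(0, (colSums(X^2) - n * mu^2) / (n - 1)))
}

drop_zero_variance <- function(X) {
  X[, col_sds(X) > 0, drop = FALSE]
}

#' Rank the features of one sub-category
#'
#' Mean Gini importance over `n_reps` forests (seeds `seed + 1 .. seed +
#' n_reps`), features ranked by the average; the top `top_k` (or all, if
#' fewer) are returned. Zero-variance features are dropped before ranking.
#'
#' @param table a [feature_table()] (the training subjects of a fold).
#' @param subcat sub-category tag.
#' @param n_reps forest repetitions.
#' @param top_k how many top features to return.
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @return Ordered character vector of feature names (possibly empty).
#' @export
rank_subcategory <- function(table, subcat, n_reps = 50, top_k = 50,
                             n_trees = 500, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  cols <- names(table$subcategory)[table$subcategory == subcat]
  if (!length(cols)) return(character(0))
  X <- drop_zero_variance(table$values[, cols, drop = FALSE])
  if (!ncol(X)) return(character(0))
  ranked <- order_by_importance(mean_importance(X, table$labels, n_reps, n_trees, seed))
  utils::head(ranked, top_k)
}

#' Pool per-sub-category rankings and re-rank
#'
#' The union of the six top lists (up to 300 features when each contributes
#' 50) is re-ranked by mean Gini importance over `n_reps` forests grown on
#' the pooled set.
#'
#' @param rankings list of ordered name vectors (disjoint across entries).
#' @param X subjects x features matrix containing at least the pooled columns.
#' @param y class labels.
#' @param n_reps,n_trees forest settings.
#' @param seed integer seed.
#' @return Ordered character vector over the pooled features.
#' @export
pool_and_rerank <- function(rankings, X, y, n_reps = 50, n_trees = 500, seed = 1L) {
  pooled <- unlist(rankings, use.names = FALSE)
  if (anyDuplicated(pooled)) stop("pooled rankings contain duplicate names")
  if (!length(pooled)) return(character(0))
  Xp <- as.matrix(X)[, pooled, drop = FALSE]
  order_by_importance(mean_importance(Xp, y, n_reps, n_trees, seed))
}

#' Incremental out-of-bag selection
#'
#' Grows forests on prefixes of the pooled ranking (most important feature
#' first, adding one at a time) and records each forest's OOB error. The
#' selected set is the shortest prefix attaining the global minimum OOB
#' error.
#'
#' @param pooled_ranking ordered feature names (nonempty).
#' @param X subjects x features matrix.
#' @param y class labels.
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @return An object of class `selection_result`: `pooled_ranking`,
#'   `oob_trace`, `selected` (a prefix of the ranking) and `seed`.
#' @export
incremental_oob_selection <- function(pooled_ranking, X, y, n_trees = 500, seed = 1L) {
  stopifnot(length(pooled_ranking) >= 1)
  X <- as.matrix(X)
  trace <- vapply(seq_along(pooled_ranking), function(m) {
    fit <- fit_forest(X[, pooled_ranking[seq_len(m)], drop = FALSE], y,
                      n_trees, seed = seed + m)
    fit$prediction.error
  }, numeric(1))
  m_star <- which.min(trace)   # first index attaining the minimum
  structure(list(pooled_ranking = pooled_ranking, oob_trace = trace,
                 selected = pooled_ranking[seq_len(m_star)], seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d pooled features selected (min OOB error %.3f)\n",
              length(x$selected), length(x$pooled_ranking), min(x$oob_trace)))
  invisible(x)
}

#' Full feature-selection stage for one training set
#'
#' Ranks each sub-category, pools the top lists, re-ranks, and runs the
#' incremental OOB minimization. Randomness is routed through three derived
#' seed streams (ranking, pooling, OOB) for auditability.
#'
#' @param table training-subject [feature_table()] (candidate filtering
#'   already applied by the caller).
#' @param n_reps,top_k,n_trees forest settings.
#' @param seed integer seed.
#' @return A `selection_result`.
#' @export
select_features <- function(table, n_reps = 50, top_k = 50, n_trees = 500,
                            seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  subcats <- intersect(FEATURE_SUBCATEGORIES, unique(table$subcategory))
  rankings <- lapply(seq_along(subcats), function(i)
    rank_subcategory(table, subcats[i], n_reps = n_reps, top_k = top_k,
                     n_trees = n_trees, seed = seed + (i - 1L) * 100L))
  pooled <- pool_and_rerank(rankings, table$values, table$labels,
                            n_reps = n_reps, n_trees = n_trees,
                            seed = seed + 1000L)
  if (!length(pooled)) stop("no usable features survive ranking")
  incremental_oob_selection(pooled, table$values, table$labels,
                            n_trees = n_trees, seed = seed + 2000L)
}
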