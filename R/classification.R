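#' Leave-one-patient-out classification
#'
#' Each subject in turn is held out; the candidate-connectivity filter, the
#' random-forest feature selection and the feature standardization statistics
#' are computed on the remaining training subjects only, a linear SVM is
#' trained on the selected features, and the held-out subject is predicted.
#' Performance is summarized as correct rate, sensitivity and specificity
#' with left-sided cases as the positive class.
#'
#' @name classification
NULL

#' Classification metrics
#'
#' @param truth,predicted equal-length label vectors (`"L"`/`"R"`).
#' @param positive the positive class (default `"L"`, left-sided).
#' @return Named list: `correct_rate` (fraction of matches), `sensitivity`
#'   `TP / (TP + FN)` and `specificity` `TN / (TN + FP)` for the positive
#'   class. A metric with an empty denominator is NA.
#' @export
evaluate_classification <- function(truth, predicted, positive = "L") {
  if (!length(truth) || length(truth) != length(predicted))
    stop("truth and predicted must be nonempty and of equal length")
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  list(correct_rate = (tp + tn) / length(truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Per-fold FC candidate screening on a feature table: FC columns must pass
# the one-sample t-test over the training subjects; other sub-categories are
# untouched.
filter_fc_candidates <- function(table, alpha) {
  fc_cols <- names(table$subcategory)[table$subcategory == "FC"]
  if (!length(fc_cols)) return(table)
  p <- one_sample_t_pvalues(table$values[, fc_cols, drop = FALSE])
  drop <- fc_cols[!(p < alpha)]
  if (!length(drop)) return(table)
  subset_features(table, setdiff(colnames(table$values), drop))
}

#' Leave-one-out cross-validation with nested feature selection
#'
#' @param table a [feature_table()] with at least 2 subjects per class.
#' @param candidate_alpha alpha for the per-fold FC candidate filter.
#' @param rf list of forest settings: `n_trees`, `n_reps`, `top_k`.
#' @param svm_c linear-SVM cost parameter.
#' @param scale_features z-score features with training-fold mean/sd before
#'   the SVM (recommended: the feature space mixes counts and ratios).
#' @param seed integer seed; each fold derives its own stream from it.
#' @return An object of class `loocv_result`: per-fold records (held-out id,
#'   truth, prediction, `selection_result`) and the summary metrics.
#' @export
loocv <- function(table, candidate_alpha = 0.05,
                  rf = list(n_trees = 500, n_reps = 50, top_k = 50),
                  svm_c = 1, scale_features = TRUE, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (min(table(table$labels)) < 2)
    stop("need at least 2 subjects per class for leave-one-out folds")
  n <- nrow(table$values)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    train <- subset_subjects(table, setdiff(seq_len(n), i))
    if (length(unique(train$labels)) < 2)
      stop("training set of a fold is single-class")
    train <- filter_fc_candidates(train, candidate_alpha)
    train <- subset_features(train,
                             colnames(train$values)[col_sds(train$values) > 0])

    sel <- select_features(train, n_reps = rf$n_reps, top_k = rf$top_k,
                           n_trees = rf$n_trees, seed = seed + i * 10000L)

    Xtr <- train$values[, sel$selected, drop = FALSE]
    Xte <- table$values[i, sel$selected, drop = FALSE]
    if (scale_features) {
      mu <- colMeans(Xtr)
      sd_ <- apply(Xtr, 2, stats::sd)
      Xtr <- scale(Xtr, center = mu, scale = sd_)
      Xte <- scale(Xte, center = mu, scale = sd_)
    }
    fit <- e1071::svm(x = Xtr, y = factor(train$labels, levels = c("L", "R")),
                      kernel = "linear", cost = svm_c, scale = FALSE)
    pred <- as.character(stats::predict(fit, Xte))

    folds[[i]] <- list(subject_id = table$subject_ids[i],
                       truth = table$labels[i], predicted = pred,
                       selection = sel)
  }
  truth <- vapply(folds, `[[`, "", "truth")
  predicted <- vapply(folds, `[[`, "", "predicted")
  structure(list(folds = folds, truth = truth, predicted = predicted,
                 summary = evaluate_classification(truth, predicted)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<loocv_result> %d folds: correct rate %.4f, sensitivity %.4f, specificity %.4f\n",
              length(x$folds), s$correct_rate, s$sensitivity, s$specificity))
  nf <- vapply(x$folds, function(f) length(f$selection$selected), numeric(1))
  cat(sprintf("  features per fold: %s (mean %.2f)\n",
              paste(nf, collapse = " "), mean(nf)))
  invisible(x)
}
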