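# Random-forest ranking, pooling and incremental OOB selection.

test_that("Gini importance finds a label-identical feature and zeroes constants", {
  set.seed(1)
  n <- 20
  labels <- rep(c("L", "R"), each = n / 2)
  X <- matrix(stats::rnorm(n * 99), n, 99)
  X <- cbind(X, oracle_col = as.numeric(labels == "L"), const = rep(1, n))
  colnames(X) <- c(sprintf("noise%02d", 1:99), "oracle_col", "const")
  wins <- sum(vapply(1:100, function(s) {
    imp <- rf_gini_importance(X, labels, n_trees = 500, seed = s)
    names(which.max(imp)) == "oracle_col"
  }, logical(1)))
  expect_gte(wins, 95)
  expect_equal(unname(rf_gini_importance(X, labels, n_trees = 100, seed = 1)["const"]), 0)
  expect_error(rf_gini_importance(X, rep("L", n), n_trees = 10), "both classes")
})

test_that("Gini importance agrees with an independent forest implementation", {
  # randomForest's MeanDecreaseGini is an independent code path for the same
  # statistic: both engines must put a planted feature far ahead of noise
  set.seed(77)
  n <- 24
  labels <- rep(c("L", "R"), each = n / 2)
  X <- cbind(matrix(stats::rnorm(n * 30), n, 30),
             planted = as.numeric(labels == "L") * 3 + stats::rnorm(n))
  colnames(X) <- c(sprintf("noise%02d", 1:30), "planted")
  imp_mine <- numeric(31)
  for (s in 1:10) imp_mine <- imp_mine + rf_gini_importance(X, labels, n_trees = 200, seed = s)
  rf <- randomForest::randomForest(x = X, y = factor(labels), ntree = 2000)
  imp_ref <- rf$importance[, "MeanDecreaseGini"]
  expect_equal(names(which.max(imp_mine)), "planted")
  expect_equal(names(which.max(imp_ref)), "planted")
  # planted importance dominates the noise ceiling in both engines
  expect_gt(imp_mine["planted"], 1.5 * max(imp_mine[1:30]))
  expect_gt(imp_ref["planted"], 1.5 * max(imp_ref[1:30]))
})

test_that("permuted labels produce no stable importance winner", {
  set.seed(2)
  n <- 20
  X <- matrix(stats::rnorm(n * 40), n, 40)
  colnames(X) <- sprintf("f%02d", 1:40)
  y_perm <- sample(rep(c("L", "R"), each = n / 2))
  total <- numeric(40)
  for (s in 1:50) total <- total + rf_gini_importance(X, y_perm, n_trees = 100, seed = s)
  mean_imp <- total / 50
  expect_lt(max(mean_imp), 3 * stats::median(mean_imp))
})

test_that("sub-category ranking surfaces a planted feature and respects top_k", {
  tb_small <- synthetic_feature_table(n_per_class = 8, n_noise = 30,
                                      planted = c(ALFF = 1))
  # the sub-category holds 5 noise features + 1 planted: all returned
  alff_cols <- names(tb_small$subcategory)[tb_small$subcategory == "ALFF"]
  ranked <- rank_subcategory(tb_small, "ALFF", n_reps = 3, top_k = 50,
                             n_trees = 100, seed = 1)
  expect_setequal(ranked, alff_cols)
  expect_identical(ranked,
                   rank_subcategory(tb_small, "ALFF", n_reps = 3, top_k = 50,
                                    n_trees = 100, seed = 1))
  expect_identical(rank_subcategory(tb_small, "fALFF", n_reps = 1, top_k = 2,
                                    n_trees = 50, seed = 1) |> length(), 2L)

  firsts <- sum(vapply(1:100, function(rep) {
    tb <- synthetic_feature_table(n_per_class = 8, n_noise = 36,
                                  planted = c(ReHo = 1), seed = rep)
    rank_subcategory(tb, "ReHo", n_reps = 3, top_k = 10,
                     n_trees = 100, seed = rep)[1] == "planted1"
  }, logical(1)))
  expect_gte(firsts, 95)
})

test_that("pooling six full top-50 lists yields 300 features, re-ranked", {
  set.seed(4)
  n <- 16
  labels <- rep(c("L", "R"), each = 8)
  X <- matrix(stats::rnorm(n * 300), n, 300)
  colnames(X) <- sprintf("f%03d", 1:300)
  rankings <- split(colnames(X), rep(1:6, each = 50))
  pooled <- pool_and_rerank(rankings, X, labels, n_reps = 1, n_trees = 50, seed = 1)
  expect_length(pooled, 300)
  expect_setequal(pooled, colnames(X))
  expect_error(pool_and_rerank(list(c("a", "b"), c("b")), X, labels), "duplicate")

  # a planted feature from any sub-category reaches the pooled top ranks
  top10 <- sum(vapply(1:100, function(rep) {
    tb <- synthetic_feature_table(n_per_class = 8, n_noise = 60,
                                  planted = c(FC = 1), seed = 200 + rep)
    rks <- lapply(restlat:::FEATURE_SUBCATEGORIES, function(s)
      rank_subcategory(tb, s, n_reps = 2, top_k = 10, n_trees = 100,
                       seed = rep))
    pooled <- pool_and_rerank(rks, tb$values, tb$labels, n_reps = 2,
                              n_trees = 100, seed = 500 + rep)
    "planted1" %in% pooled[1:10]
  }, logical(1)))
  expect_gte(top10, 90)
})

test_that("incremental OOB selection returns the shortest minimal prefix", {
  # a perfectly separating feature first: one feature suffices
  singles <- sum(vapply(1:100, function(rep) {
    set.seed(rep)
    n <- 16
    labels <- rep(c("L", "R"), each = 8)
    X <- cbind(sep = as.numeric(labels == "L") + stats::rnorm(n, sd = 0.05),
               matrix(stats::rnorm(n * 19), n, 19))
    colnames(X) <- c("sep", sprintf("n%02d", 1:19))
    sel <- incremental_oob_selection(colnames(X), X, labels,
                                     n_trees = 100, seed = rep)
    length(sel$selected) == 1
  }, logical(1)))
  expect_gte(singles, 90)

  # flat OOB trace (three copies of a perfect separator): tie broken at 1
  labels <- rep(c("L", "R"), each = 6)
  Xf <- cbind(a = as.numeric(labels == "L"), b = as.numeric(labels == "L"),
              c = as.numeric(labels == "L"))
  self <- incremental_oob_selection(c("a", "b", "c"), Xf, labels,
                                    n_trees = 100, seed = 3)
  expect_equal(length(self$selected), 1)
  expect_equal(max(self$oob_trace), min(self$oob_trace))
})

test_that("selection results are prefixes and pure functions of data and seed", {
  tb <- synthetic_feature_table(n_per_class = 6, n_noise = 48,
                                planted = c(ALFF = 1, FC = 1))
  sel1 <- select_features(tb, n_reps = 2, top_k = 5, n_trees = 100, seed = 9)
  sel2 <- select_features(tb, n_reps = 2, top_k = 5, n_trees = 100, seed = 9)
  expect_identical(sel1, sel2)
  expect_identical(sel1$selected,
                   sel1$pooled_ranking[seq_along(sel1$selected)])
  expect_equal(sel1$oob_trace[length(sel1$selected)], min(sel1$oob_trace))
  expect_equal(which.min(sel1$oob_trace), length(sel1$selected))
})
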