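test_that("undersampling balances to the minority size, deterministically", {
  rows <- toy_features(40)[c(rep(TRUE, 40), rep(TRUE, 12), rep(FALSE, 28)), ]
  b <- balance_by_undersampling(rows, seed = 3)
  expect_equal(as.integer(table(b$label)), c(12L, 12L))
  expect_true(all(b$record_id[b$label == "pre_appropriate_shock"] %in% rows$record_id))
  b2 <- balance_by_undersampling(rows, seed = 3)
  expect_identical(b, b2)
  already <- toy_features(15)
  expect_setequal(balance_by_undersampling(already, 1)$record_id, already$record_id)
  expect_error(balance_by_undersampling(already[already$label == "regular", ], 1),
               "both classes")
})

test_that("the stratified split is a disjoint exhaustive per-class partition", {
  rows <- toy_features(25)
  sp <- split_train_test(rows, 0.8, seed = 2)
  expect_equal(sort(c(sp$train$record_id, sp$test$record_id)), sort(rows$record_id))
  expect_length(intersect(sp$train$record_id, sp$test$record_id), 0)
  expect_equal(as.integer(table(sp$train$label)), c(20L, 20L))
  sp2 <- split_train_test(rows, 0.8, seed = 2)
  expect_identical(sp$train$record_id, sp2$train$record_id)
  expect_error(split_train_test(toy_features(3), 0.8, 1), "at least 5")
})

test_that("random forest separates separable data and scores deterministically", {
  rows <- toy_features(30, delta = 6)
  rf <- train_random_forest(rows, c("f1", "f2"), seed = 1, ntree = 200)
  scores <- predict_scores(rf, rows)
  pred <- scores > decision_threshold(rf)
  expect_equal(mean(pred == (rows$label == "pre_appropriate_shock")), 1)
  rf2 <- train_random_forest(rows, c("f1", "f2"), seed = 1, ntree = 200)
  expect_identical(predict_scores(rf2, rows), scores)
  expect_error(train_random_forest(rows[rows$label == "regular", ], c("f1", "f2")),
               "both classes")
})

test_that("null-label forests and SVMs give chance-level AUC", {
  set.seed(5)
  aucs_rf <- aucs_svm <- numeric(20)
  for (i in 1:20) {
    rows <- toy_features(25, seed = i, delta = 0)   # labels carry no signal
    sp <- split_train_test(rows, 0.8, seed = i)
    rf <- train_random_forest(sp$train, c("f1", "f2", "f3"), seed = i, ntree = 150)
    aucs_rf[i] <- roc_auc(predict_scores(rf, sp$test), sp$test$label)
    sv <- train_linear_svm(sp$train, c("f1", "f2", "f3"), seed = i)
    aucs_svm[i] <- roc_auc(predict_scores(sv, sp$test), sp$test$label)
  }
  expect_lt(abs(mean(aucs_rf) - 0.5), 0.1)
  expect_lt(abs(mean(aucs_svm) - 0.5), 0.1)
})

test_that("the linear SVM standardizes with training statistics only", {
  rows <- toy_features(30, delta = 4)
  sv <- train_linear_svm(rows, c("f1", "f2"), seed = 1)
  expect_equal(sv$center, colMeans(as.matrix(rows[, c("f1", "f2")])))
  expect_equal(sv$scale, apply(as.matrix(rows[, c("f1", "f2")]), 2, sd))
  # margins separate the separable training set at 0
  m <- predict_scores(sv, rows)
  expect_true(all(m[rows$label == "pre_appropriate_shock"] > 0))
  expect_true(all(m[rows$label == "regular"] < 0))
  # a row's score does not depend on which other rows are scored with it
  expect_equal(predict_scores(sv, rows[1, ]), predict_scores(sv, rows)[1])
})

test_that("rank-based AUC equals the pair-counting oracle and flips with labels", {
  pair_auc <- function(s, pos) {
    sp <- s[pos]; sn <- s[!pos]
    tot <- 0
    for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
  }
  set.seed(13)
  for (i in 1:5) {
    s <- sample(round(rnorm(20), 1))      # rounding forces some ties
    pos <- rep(c(TRUE, FALSE), 10)
    expect_equal(roc_auc(s, pos), pair_auc(s, pos))
    expect_equal(roc_auc(s, !pos), 1 - roc_auc(s, pos))
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(1:3, rep(TRUE, 3)), "both classes")
})

test_that("sensitivity and specificity follow the 2x2 table", {
  ss <- sensitivity_specificity(rep(TRUE, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(ss, list(sensitivity = 1, specificity = 0))
  truth <- c(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(sensitivity_specificity(truth, truth),
               list(sensitivity = 1, specificity = 1))
  pred <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  ss2 <- sensitivity_specificity(pred, truth)   # TP=3 FN=1 TN=2 FP=2
  expect_equal(ss2, list(sensitivity = 0.75, specificity = 0.5))
})

test_that("permutation importance isolates informative predictors", {
  set.seed(17)
  imps <- replicate(10, {
    rows <- toy_features(50, seed = sample.int(1e6, 1), delta = 4)
    rf <- train_random_forest(rows, c("f1", "f2", "f3"), seed = 1, ntree = 300)
    permutation_importance(rf)$importance
  })
  expect_true(all(apply(imps, 2, which.max) == 1))
  expect_lt(max(abs(imps[2:3, ])), 0.02)
})

test_that("Mann-Whitney matches exact enumeration and reports summaries", {
  gt <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gt$p_value, 0.1)
  expect_equal(gt$statistic, 0)
  expect_equal(gt$median_a, 2)
  same <- mann_whitney_u(1:30, 1:30)
  expect_gte(same$p_value, 0.9)
  # normal approximation within 10% of exact enumeration at n = 9
  exact_p <- function(a, b) {
    pool <- c(a, b); n1 <- length(a)
    u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- combn(length(pool), n1)
    us <- apply(combs, 2, function(idx) {
      sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * length(b) / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  set.seed(23)
  for (i in 1:5) {
    a <- rnorm(9); b <- rnorm(9, 0.8)
    p_pkg <- mann_whitney_u(a, b)$p_value
    p_ex <- exact_p(a, b)
    expect_lt(abs(p_pkg - p_ex), 0.1 * p_ex)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("group statistics cover the ten features on both classes", {
  co <- small_cohort(25, 25, seed = 31)
  feats <- small_features(co)
  gs <- group_stats(feats)
  expect_equal(nrow(gs), 10)
  expect_setequal(gs$feature, scalar_feature_names())
  expect_true(all(gs$p_value > 0 & gs$p_value <= 1))
  f <- gs$feature[1]
  expect_equal(gs$regular_median[1],
               median(feats[[f]][feats$label == "regular"]))
  expect_error(group_stats(feats[feats$label == "regular", ]), "both classes")
})
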