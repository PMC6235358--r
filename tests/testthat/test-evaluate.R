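co <- small_cohort(40, 40, seed = 21)
feats <- small_features(co, m = 256)

test_that("a single-trial run equals the manual composition at the derived seed", {
  cfg <- eval_config("five_minute", window_m = 256, n_trials = 1, seed = 10,
                     classifiers = "random_forest", ntree = 100)
  ev <- run_evaluation(feats, cfg)
  # manual pass with the same derived seed (config seed + trial index)
  b <- balance_by_undersampling(feats, seed = 11)
  sp <- split_train_test(b, 0.8, seed = 11)
  d <- fit_decomposition(assemble_matrix(sp$train$window))
  addpc <- function(rows) {
    pcs <- t(vapply(rows$window, function(w) project_record(d, w), numeric(d$k)))
    colnames(pcs) <- paste0("pc", seq_len(d$k))
    dplyr::bind_cols(rows, tibble::as_tibble(pcs))
  }
  rf <- train_random_forest(addpc(sp$train),
                            c(paste0("pc", seq_len(d$k)), scalar_feature_names()),
                            seed = 11, ntree = 100)
  scores <- predict_scores(rf, addpc(sp$test))
  expect_equal(ev$per_trial$auc, roc_auc(scores, sp$test$label))
  expect_equal(ev$aggregate$sd, rep(0, 3))
})

test_that("aggregates equal the mean of per-trial metrics and stay in range", {
  cfg <- eval_config("five_minute", window_m = 256, n_trials = 5, seed = 2,
                     ntree = 100)
  ev <- run_evaluation(feats, cfg)
  expect_equal(nrow(ev$per_trial), 10)   # 5 trials x 2 classifiers
  for (clf in c("random_forest", "linear_svm")) {
    for (met in c("sensitivity", "specificity", "auc")) {
      agg <- ev$aggregate
      expect_equal(agg$mean[agg$classifier == clf & agg$metric == met],
                   mean(ev$per_trial[[met]][ev$per_trial$classifier == clf]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(ev$per_trial$auc >= 0 & ev$per_trial$auc <= 1))
  expect_true(all(ev$aggregate$sd >= 0))
})

test_that("repeated runs with one config are identical", {
  cfg <- eval_config("five_minute", window_m = 256, n_trials = 3, seed = 4,
                     classifiers = "random_forest", ntree = 100)
  e1 <- run_evaluation(feats, cfg)
  e2 <- run_evaluation(feats, cfg)
  expect_identical(e1$per_trial, e2$per_trial)
  expect_identical(e1$importance, e2$importance)
})

test_that("importance is reported in the standard predictor ordering", {
  cfg <- eval_config("five_minute", window_m = 256, n_trials = 2, seed = 6,
                     classifiers = "random_forest", ntree = 100)
  ev <- run_evaluation(feats, cfg)
  k <- max(ev$k)
  expect_equal(ev$importance$predictor,
               c(paste0("pc", seq_len(k)), scalar_feature_names()))
  expect_equal(nrow(ev$importance), k + 10)
})

test_that("swapping the class generators swaps sensitivity and specificity", {
  specs <- default_class_specs()
  swapped <- list(
    regular = specs$pre_appropriate_shock,
    pre_appropriate_shock = specs$regular
  )
  swapped$regular$label <- "regular"
  swapped$regular$surge <- NULL
  swapped$pre_appropriate_shock$label <- "pre_appropriate_shock"
  co_sw <- generate_cohort(cohort_spec(40, 40, n_beats = 1024, seed = 21,
                                       class_specs = swapped))
  feats_sw <- small_features(co_sw, m = 256)
  cfg <- eval_config("five_minute", window_m = 256, n_trials = 6, seed = 3,
                     classifiers = "random_forest", ntree = 150)
  agg <- function(ev, met) {
    a <- ev$aggregate; a$mean[a$metric == met]
  }
  ev <- run_evaluation(feats, cfg)
  ev_sw <- run_evaluation(feats_sw, cfg)
  expect_equal(agg(ev, "sensitivity"), agg(ev_sw, "specificity"), tolerance = 0.2)
  expect_equal(agg(ev, "specificity"), agg(ev_sw, "sensitivity"), tolerance = 0.2)
})

test_that("degenerate cohorts abort once more than 10% of trials fail", {
  bad <- feats
  bad$window <- lapply(bad$window, function(w) rep(0.8, length(w)))
  cfg <- eval_config("five_minute", window_m = 256, n_trials = 3, seed = 1,
                     classifiers = "random_forest")
  expect_error(run_evaluation(bad, cfg), "trials failed")
})

test_that("tidy, glance and autoplot expose the evaluation", {
  cfg <- eval_config("five_minute", window_m = 256, n_trials = 2, seed = 8,
                     classifiers = "random_forest", ntree = 100)
  ev <- run_evaluation(feats, cfg)
  expect_identical(tidy(ev), ev$per_trial)
  g <- glance(ev)
  expect_equal(g$horizon, "five_minute")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(plot_importance(ev), "ggplot")
})
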