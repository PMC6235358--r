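#' Balance classes by undersampling the majority class
#'
#' The regular-rhythm class outnumbers the pre-shock class by roughly 29:1
#' in the study design, which would bias any classifier trained on the raw
#' rows. The minority class is kept whole and the majority class is
#' sampled without replacement down to the minority size.
#'
#' @param rows A tibble with a `label` column (two classes).
#' @param seed Integer seed making the draw reproducible.
#' @return A tibble with equal class counts (minority rows first).
#' @export
balance_by_undersampling <- function(rows, seed = 1L) {
  counts <- table(rows$label)
  if (length(counts) != 2L || any(counts == 0L)) {
    stop("both classes must be present", call. = FALSE)
  }
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(names(counts), minority)
  n_min <- min(counts)
  maj_idx <- which(rows$label == majority)
  set.seed(seed)
  keep <- sort(sample(maj_idx, n_min))
  dplyr::bind_rows(rows[rows$label == minority, ], rows[keep, ])
}

#' Stratified train/test split
#'
#' Splits rows into training and test sets, stratified by class: each
#' class contributes `round(train_fraction * class size)` rows to
#' training. The split is disjoint and exhaustive.
#'
#' @param rows A tibble with a `label` column.
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(rows, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- table(rows$label)
  if (any(counts < 5L)) stop("each class needs at least 5 rows", call. = FALSE)
  set.seed(seed)
  train_idx <- unlist(lapply(names(counts), function(cl) {
    idx <- which(rows$label == cl)
    sample(idx, round(train_fraction * length(idx)))
  }), use.names = FALSE)
  train_idx <- sort(train_idx)
  list(train = rows[train_idx, ], test = rows[-train_idx, ])
}

# positive class label used throughout the classifier stack
positive_class <- function() "pre_appropriate_shock"

as_design_matrix <- function(rows, predictors) {
  missing <- setdiff(predictors, names(rows))
  if (length(missing)) {
    stop(sprintf("rows lack predictor column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as.matrix(rows[, predictors])
}

#' Train a random forest on labelled feature rows
#'
#' Bagged ensemble of decision trees (default 500) with a random subset
#' of `sqrt(p)` candidate predictors at each split. The continuous score
#' of a row is the fraction of trees voting for the positive (pre-shock)
#' class; the class decision uses threshold 0.5. Out-of-bag permutation
#' importances (mean increase in prediction error when a predictor is
#' permuted across out-of-bag records, averaged over trees) are recorded
#' at training time.
#'
#' @param train A tibble with a two-class `label` column and predictor
#'   columns.
#' @param predictors Character vector of predictor column names.
#' @param seed Integer seed (forest growth is stochastic).
#' @param ntree Number of trees (default 500).
#' @return An object of class `vt_rf` with elements `fit`, `predictors`;
#'   score rows with [predict_scores()].
#' @export
train_random_forest <- function(train, predictors = scalar_feature_names(),
                                seed = 1L, ntree = 500L) {
  if (length(unique(train$label)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- as_design_matrix(train, predictors)
  y <- factor(train$label == positive_class(), levels = c(FALSE, TRUE),
              labels = c("neg", "pos"))
  set.seed(seed)
  fit <- randomForest::randomForest(X, y, ntree = ntree, importance = TRUE)
  structure(list(fit = fit, predictors = predictors), class = "vt_rf")
}

#' Train a linear support-vector machine on labelled feature rows
#'
#' Maximum-margin linear classifier (cost parameter default 1) on
#' normalized data: each predictor is standardized by subtracting the
#' training mean and dividing by the training standard deviation;
#' the stored training statistics are reused to standardize test rows
#' (test rows never contribute to the normalization). The continuous
#' score is the signed decision margin, oriented so positive margins
#' favour the pre-shock class; the class decision is taken at margin 0.
#'
#' @inheritParams train_random_forest
#' @param cost SVM regularization constant (default 1).
#' @return An object of class `vt_svm`.
#' @export
train_linear_svm <- function(train, predictors = scalar_feature_names(),
                             seed = 1L, cost = 1) {
  if (length(unique(train$label)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- as_design_matrix(train, predictors)
  y <- factor(train$label == positive_class(), levels = c(FALSE, TRUE),
              labels = c("neg", "pos"))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  set.seed(seed)
  fit <- e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE)
  # orient the margin so that positive values favour the "pos" class
  dv <- attr(stats::predict(fit, Xs, decision.values = TRUE), "decision.values")
  orient <- if (grepl("^pos/", colnames(dv)[1])) 1 else -1
  structure(list(fit = fit, predictors = predictors, center = center,
                 scale = scale, orient = orient), class = "vt_svm")
}

#' Score feature rows with a trained classifier
#'
#' @param model A `vt_rf` or `vt_svm`.
#' @param rows A tibble containing the model's predictor columns.
#' @return Numeric scores: tree vote fraction in \[0, 1\] for the forest,
#'   signed margin for the SVM. Higher means more pre-shock-like.
#' @export
predict_scores <- function(model, rows) {
  X <- as_design_matrix(rows, model$predictors)
  if (inherits(model, "vt_rf")) {
    unname(stats::predict(model$fit, X, type = "prob")[, "pos"])
  } else if (inherits(model, "vt_svm")) {
    Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
    dv <- attr(stats::predict(model$fit, Xs, decision.values = TRUE),
               "decision.values")
    unname(model$orient * dv[, 1])
  } else {
    stop("unknown model class", call. = FALSE)
  }
}

#' @rdname predict_scores
#' @export
decision_threshold <- function(model) {
  if (inherits(model, "vt_rf")) 0.5 else 0
}

#' Area under the ROC curve
#'
#' Computed through the rank (Mann-Whitney) identity with midranks for
#' ties, which equals the trapezoidal area under the empirical ROC curve:
#' the probability that a randomly chosen positive outscores a randomly
#' chosen negative, counting ties as 1/2.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical or label vector; `TRUE` / the positive class
#'   marks positives.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) labels
  else labels == positive_class() | labels %in% c("pos", "1", "TRUE")
}

#' Sensitivity and specificity of hard class decisions
#'
#' Sensitivity is the fraction of pre-shock (positive) records classified
#' correctly, `TP / (TP + FN)`; specificity the fraction of regular
#' (negative) records classified correctly, `TN / (TN + FP)`.
#'
#' @param predictions Logical/label vector of predicted classes.
#' @param labels Logical/label vector of true classes.
#' @return A named list with `sensitivity` and `specificity`.
#' @export
sensitivity_specificity <- function(predictions, labels) {
  truth <- as_positive(labels)
  pred <- as_positive(predictions)
  if (!any(truth) || all(truth)) stop("both classes must be present", call. = FALSE)
  list(sensitivity = sum(pred & truth) / sum(truth),
       specificity = sum(!pred & !truth) / sum(!truth))
}

#' Out-of-bag permutation importance of a trained forest
#'
#' For each predictor, the mean over trees of the increase in out-of-bag
#' prediction error when that predictor's values are permuted across the
#' out-of-bag records (the raw, unscaled mean decrease in accuracy).
#'
#' @param forest A `vt_rf` from [train_random_forest()].
#' @return A tibble with `predictor` and `importance`, in the model's
#'   predictor order.
#' @export
permutation_importance <- function(forest) {
  stopifnot(inherits(forest, "vt_rf"))
  imp <- randomForest::importance(forest$fit, type = 1, scale = FALSE)
  tibble::tibble(predictor = forest$predictors,
                 importance = unname(imp[forest$predictors, 1]))
}

#' Mann-Whitney U test with group summaries
#'
#' Two-sided rank-sum comparison of one feature between the two rhythm
#' groups, reported with group medians and interquartile ranges. Exact
#' enumeration is used when the smaller group has 8 or fewer observations
#' and the data are tie-free; otherwise the tie-corrected normal
#' approximation (with continuity correction) is used.
#'
#' @param group_a,group_b Numeric vectors.
#' @return A one-row tibble: medians, IQR bounds, `statistic` (U for
#'   `group_a`) and `p_value`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  use_exact <- min(length(group_a), length(group_b)) <= 8L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact, correct = TRUE)
  )
  qa <- stats::quantile(group_a, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- stats::quantile(group_b, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    median_a = qa[2], iqr_lo_a = qa[1], iqr_hi_a = qa[3],
    median_b = qb[2], iqr_lo_b = qb[1], iqr_hi_b = qb[3],
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
}

#' Per-feature group statistics table
#'
#' One row per scalar feature: median (IQR) in each rhythm class and the
#' two-sided Mann-Whitney p-value, computed on the full (unbalanced)
#' cohort.
#'
#' @param features A feature tibble from [extract_features()].
#' @return A tibble with one row per feature.
#' @export
group_stats <- function(features) {
  classes <- unique(features$label)
  if (length(classes) < 2L) stop("both classes must be present", call. = FALSE)
  reg <- features[features$label == "regular", ]
  pre <- features[features$label == positive_class(), ]
  purrr::map_dfr(scalar_feature_names(), function(f) {
    gt <- mann_whitney_u(reg[[f]], pre[[f]])
    tibble::tibble(
      feature = f,
      regular_median = gt$median_a, regular_iqr_lo = gt$iqr_lo_a,
      regular_iqr_hi = gt$iqr_hi_a,
      preshock_median = gt$median_b, preshock_iqr_lo = gt$iqr_lo_b,
      preshock_iqr_hi = gt$iqr_hi_b,
      statistic = gt$statistic, p_value = gt$p_value
    )
  })
}
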