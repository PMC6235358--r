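#' Evaluation protocol configuration
#'
#' @param horizon `"five_minute"` or `"ten_second"`.
#' @param window_m Window length in beats; defaults to 1000 / 1600 to
#'   match the horizon.
#' @param n_trials Number of repeated balanced resampling trials
#'   (default 100).
#' @param train_fraction Training fraction of the balanced sample
#'   (default 0.8).
#' @param seed Master seed; trial `i` uses `seed + i` so any trial is
#'   individually reproducible.
#' @param classifiers Subset of `c("random_forest", "linear_svm")`.
#' @param ntree,cost Random-forest tree count and SVM cost.
#' @param patient_grouped If `TRUE`, the train/test split keeps all of a
#'   patient's records on the same side (the leakage-safe alternative to
#'   the default record-level split).
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(horizon = c("five_minute", "ten_second"),
                        window_m = NULL, n_trials = 100L,
                        train_fraction = 0.8, seed = 1L,
                        classifiers = c("random_forest", "linear_svm"),
                        ntree = 500L, cost = 1,
                        patient_grouped = FALSE) {
  horizon <- match.arg(horizon)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  stopifnot(n_trials >= 1L, train_fraction > 0, train_fraction < 1)
  structure(
    list(horizon = horizon,
         window_m = if (is.null(window_m)) default_window_m(horizon) else as.integer(window_m),
         n_trials = as.integer(n_trials), train_fraction = train_fraction,
         seed = as.integer(seed), classifiers = classifiers,
         ntree = as.integer(ntree), cost = cost,
         patient_grouped = isTRUE(patient_grouped)),
    class = "eval_config"
  )
}

# Fig 3/4 predictor ordering: PC 1..k, alpha1, alpha2, mean N-N,
# bins 1-5 (low to high), complexity, mobility.
predictor_order <- function(k) c(paste0("pc", seq_len(k)), scalar_feature_names())

run_single_trial <- function(features, config, trial_seed) {
  balanced <- balance_by_undersampling(features, seed = trial_seed)
  split <- if (config$patient_grouped) {
    split_by_patient(balanced, config$train_fraction, seed = trial_seed)
  } else {
    split_train_test(balanced, config$train_fraction, seed = trial_seed)
  }
  train <- split$train
  test <- split$test

  # PCA is refit on the training windows of every trial; test windows are
  # projected with the training-set decomposition and never influence it.
  std <- assemble_matrix(train$window, ids = train$record_id)
  decomp <- fit_decomposition(std)
  add_pcs <- function(rows) {
    pcs <- t(vapply(rows$window, function(w) project_record(decomp, w),
                    numeric(decomp$k)))
    if (decomp$k == 1L) pcs <- matrix(unlist(pcs), ncol = 1L)
    colnames(pcs) <- paste0("pc", seq_len(decomp$k))
    dplyr::bind_cols(rows, tibble::as_tibble(pcs))
  }
  train <- add_pcs(train)
  test <- add_pcs(test)
  predictors <- predictor_order(decomp$k)

  metrics <- list()
  importance <- NULL
  for (clf in config$classifiers) {
    model <- if (clf == "random_forest") {
      train_random_forest(train, predictors, seed = trial_seed, ntree = config$ntree)
    } else {
      train_linear_svm(train, predictors, seed = trial_seed, cost = config$cost)
    }
    scores <- predict_scores(model, test)
    pred <- scores > decision_threshold(model)
    ss <- sensitivity_specificity(pred, test$label)
    metrics[[clf]] <- tibble::tibble(
      classifier = clf,
      sensitivity = ss$sensitivity, specificity = ss$specificity,
      auc = roc_auc(scores, test$label)
    )
    if (clf == "random_forest") {
      importance <- permutation_importance(model)
    }
  }
  list(metrics = dplyr::bind_rows(metrics), importance = importance, k = decomp$k)
}

split_by_patient <- function(rows, train_fraction, seed = 1L) {
  set.seed(seed)
  patients <- unique(rows$patient_id)
  train_pat <- sample(patients, round(train_fraction * length(patients)))
  list(train = rows[rows$patient_id %in% train_pat, ],
       test = rows[!rows$patient_id %in% train_pat, ])
}

#' Run the balanced repeated-resampling evaluation
#'
#' The warning-system evaluation protocol: in each trial the majority
#' class is undersampled to the minority size, the balanced sample is
#' split 80/20 stratified by class, the tachogram PCA (with Gavish-Donoho
#' rank selection) is fitted on the training windows only, every row is
#' augmented with its retained principal-component coefficients, the
#' requested classifiers are trained and the held-out test rows scored.
#' Per-trial sensitivity, specificity and AUC are aggregated as mean (SD)
#' over trials; random-forest out-of-bag permutation importances are
#' averaged over trials in the fixed predictor ordering PC 1..k, alpha1,
#' alpha2, mean N-N, band powers 1-5, complexity, mobility.
#'
#' A trial that fails (e.g. a degenerate record) is recorded and skipped;
#' the run aborts if more than 10% of trials fail.
#'
#' @param features A feature tibble from [extract_features()] (must
#'   retain the `window` list-column).
#' @param config An [eval_config()].
#' @return An object of class `vt_eval`: list with tibbles `per_trial`,
#'   `aggregate`, `importance`, the `config`, per-trial retained ranks
#'   `k`, and `n_failed`.
#' @export
run_evaluation <- function(features, config = eval_config()) {
  stopifnot(inherits(config, "eval_config"))
  per_trial <- vector("list", config$n_trials)
  importances <- vector("list", config$n_trials)
  ks <- integer(config$n_trials)
  failed <- character(0)
  for (i in seq_len(config$n_trials)) {
    res <- tryCatch(run_single_trial(features, config, config$seed + i),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("trial %d: %s", i, conditionMessage(res)))
      next
    }
    per_trial[[i]] <- dplyr::mutate(res$metrics, trial = i, .before = 1)
    importances[[i]] <- dplyr::mutate(res$importance, trial = i)
    ks[i] <- res$k
  }
  if (length(failed) > 0.1 * config$n_trials) {
    stop(sprintf("more than 10%% of trials failed:\n%s",
                 paste(utils::head(failed, 5), collapse = "\n")), call. = FALSE)
  }
  per_trial <- dplyr::bind_rows(per_trial)
  aggregate <- per_trial |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$classifier, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     .groups = "drop")
  importance <- dplyr::bind_rows(importances) |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(importance = mean(.data$importance),
                     n_trials = dplyr::n(), .groups = "drop")
  k_max <- max(c(ks, 1L))
  importance <- importance[order(match(importance$predictor, predictor_order(k_max))), ]
  structure(
    list(per_trial = per_trial, aggregate = aggregate, importance = importance,
         config = config, k = ks[ks > 0], n_failed = length(failed),
         failures = failed),
    class = "vt_eval"
  )
}

#' @export
print.vt_eval <- function(x, ...) {
  cat(sprintf("<vt_eval> %s horizon, %d trials (%d failed)\n",
              x$config$horizon, x$config$n_trials, x$n_failed))
  agg <- tidyr::pivot_wider(x$aggregate, names_from = "metric",
                            values_from = c("mean", "sd"))
  print(as.data.frame(agg), digits = 3)
  invisible(x)
}

#' @method tidy vt_eval
#' @export
tidy.vt_eval <- function(x, ...) x$per_trial

#' @method glance vt_eval
#' @export
glance.vt_eval <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregate, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::mutate(wide, horizon = x$config$horizon,
                n_trials = x$config$n_trials, .before = 1)
}

#' Metric distributions across trials
#'
#' @param object A `vt_eval`.
#' @param ... Unused.
#' @return A ggplot: per-trial metric distributions by classifier.
#' @method autoplot vt_eval
#' @export
autoplot.vt_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_trial,
                           c("sensitivity", "specificity", "auc"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$classifier, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = NULL, x = NULL,
                  title = sprintf("Test-set performance over %d balanced trials (%s)",
                                  object$config$n_trials, object$config$horizon)) +
    ggplot2::theme_minimal()
}

#' Mean predictor importance in the standard ordering
#'
#' @param object A `vt_eval` run including the random forest.
#' @return A ggplot of mean out-of-bag permutation importance per
#'   predictor, ordered PC 1..k then the scalar features.
#' @export
plot_importance <- function(object) {
  stopifnot(inherits(object, "vt_eval"))
  d <- object$importance
  d$predictor <- factor(d$predictor, levels = d$predictor)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predictor, y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean OOB permutation importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
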