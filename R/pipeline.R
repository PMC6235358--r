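#' Pipeline step: simulate a cohort to disk
#'
#' Generates a synthetic cohort, writes the record files and manifest to
#' `out_dir`, and (optionally, on a per-class subsample) writes a
#' calibration report CSV comparing the synthetic feature marginals with
#' the published reference.
#'
#' @param cspec A [cohort_spec].
#' @param out_dir Output directory.
#' @param calibration_n Per-class subsample size for the calibration
#'   report (0 disables the report).
#' @param horizon Horizon used for the calibration report.
#' @return Invisibly, a list with the cohort tibble, the manifest path
#'   and the calibration report (or `NULL`).
#' @export
pipeline_simulate <- function(cspec, out_dir, calibration_n = 200L,
                              horizon = "five_minute") {
  cohort <- generate_cohort(cspec)
  manifest <- write_cohort(cohort, out_dir)
  report <- NULL
  if (calibration_n > 0) {
    sub <- dplyr::slice_head(dplyr::group_by(cohort, .data$rhythm_class),
                             n = calibration_n)
    report <- calibration_report(dplyr::ungroup(sub), horizon)
    utils::write.csv(report, file.path(out_dir, "calibration.csv"),
                     row.names = FALSE)
  }
  message(sprintf("simulated %d records (%s) -> %s",
                  nrow(cohort), attr(cohort, "provenance"), out_dir))
  invisible(list(cohort = cohort, manifest = manifest, calibration = report))
}

#' Pipeline step: extract scalar features for a cohort
#'
#' Applies ectopy filtering, the minimum-normal-beats inclusion rule and
#' pre-event windowing, then computes the ten scalar HRV features per
#' surviving record. Excluded records are written to an exclusion log
#' (one line per record with a machine-readable reason code).
#'
#' @param cohort A cohort tibble, or a path accepted by [read_cohort()].
#' @param horizon `"five_minute"` or `"ten_second"`.
#' @param out_csv Optional path for the feature CSV.
#' @param m,min_normal Windowing overrides (see [window_cohort()]).
#' @return The feature tibble (invisibly if `out_csv` is given), with the
#'   exclusion log in the `"exclusions"` attribute.
#' @export
pipeline_features <- function(cohort, horizon = c("five_minute", "ten_second"),
                              out_csv = NULL, m = NULL, min_normal = 1700L) {
  horizon <- match.arg(horizon)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  windowed <- window_cohort(cohort, horizon, m, min_normal)
  excl <- attr(windowed, "exclusions")
  if (nrow(excl)) {
    for (i in seq_len(nrow(excl))) {
      message(sprintf("excluded %s: %s", excl$record_id[i], excl$reason[i]))
    }
  }
  if (!nrow(windowed)) stop("no records survive inclusion and windowing", call. = FALSE)
  feats <- extract_features(windowed)
  if (!is.null(out_csv)) {
    utils::write.csv(feats[, setdiff(names(feats), "window")], out_csv,
                     row.names = FALSE)
    writeLines(sprintf("%s\t%s", excl$record_id, excl$reason),
               paste0(out_csv, ".exclusions.tsv"))
    return(invisible(feats))
  }
  feats
}

#' Pipeline step: run the evaluation and write reports
#'
#' Runs [run_evaluation()] (per-trial PCA refit included) and writes the
#' metrics JSON (config echo, per-trial arrays, aggregate mean/SD,
#' importance vector), a performance-table CSV (mean (SD) of
#' sensitivity/specificity/AUC per classifier) and the mean importance
#' CSV in the standard predictor ordering.
#'
#' @param features A feature tibble from [pipeline_features()] /
#'   [extract_features()] (with `window` list-column).
#' @param config An [eval_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return The `vt_eval` object.
#' @export
pipeline_evaluate <- function(features, config = eval_config(), out_dir = NULL) {
  ev <- run_evaluation(features, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    payload <- list(
      config = unclass(config),
      per_trial = ev$per_trial,
      aggregate = ev$aggregate,
      importance = ev$importance,
      n_failed = ev$n_failed
    )
    jsonlite::write_json(payload, file.path(out_dir, "metrics.json"),
                         digits = NA, auto_unbox = TRUE, dataframe = "columns")
    agg <- tidyr::pivot_wider(ev$aggregate, names_from = "metric",
                              values_from = c("mean", "sd"))
    utils::write.csv(agg, file.path(out_dir, "performance.csv"), row.names = FALSE)
    utils::write.csv(ev$importance, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
  }
  ev
}

#' Pipeline step: group-statistics table
#'
#' One row per scalar feature: median (IQR) in each rhythm class and the
#' two-sided Mann-Whitney p-value, computed on the full (unbalanced)
#' feature table.
#'
#' @param features A feature tibble, or path to a feature CSV written by
#'   [pipeline_features()].
#' @param out_csv Optional output path.
#' @return The group-statistics tibble.
#' @export
pipeline_group_stats <- function(features, out_csv = NULL) {
  if (is.character(features)) {
    features <- tibble::as_tibble(utils::read.csv(features))
  }
  gs <- group_stats(features)
  if (!is.null(out_csv)) utils::write.csv(gs, out_csv, row.names = FALSE)
  gs
}
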