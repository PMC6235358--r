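#' Remove ectopic beats and compensatory pauses from a record
#'
#' Device tachograms are cleaned before N-N analysis so that premature
#' ventricular contractions and their compensatory pauses do not inflate
#' the variability estimates. Two rules are applied in a single ordered
#' pass; a beat survives only if it passes both:
#'
#' * label rule: beats annotated `"V"` or `"P"` are removed;
#' * timing rule: an `"N"`-labelled interval deviating by more than 20%
#'   from the running median of the previous 5 *accepted* intervals is
#'   removed together with the immediately following interval (treated as
#'   its compensatory pause). The rule is inactive until 5 intervals have
#'   been accepted.
#'
#' Because every decision depends only on previously accepted beats, the
#' filter is idempotent: filtering twice equals filtering once.
#'
#' @param record An [rr_record] with at least one beat.
#' @param tolerance Fractional deviation from the running median that
#'   triggers the timing rule (default 0.2).
#' @param memory Number of previous accepted intervals in the running
#'   median (default 5).
#' @return An [rr_record] containing the surviving beats, in order.
#' @export
filter_ectopic_beats <- function(record, tolerance = 0.2, memory = 5L) {
  stopifnot(is_rr_record(record))
  iv <- record$beats$interval
  lab <- record$beats$label
  n <- length(iv)
  if (n == 0L) stop("cannot filter an empty record", call. = FALSE)
  keep <- logical(n)
  accepted <- numeric(n)
  n_acc <- 0L
  skip_next <- FALSE
  for (i in seq_len(n)) {
    if (lab[i] != "N") next
    if (skip_next) {
      skip_next <- FALSE
      next
    }
    if (n_acc >= memory) {
      med <- stats::median(accepted[(n_acc - memory + 1L):n_acc])
      if (abs(iv[i] - med) > tolerance * med) {
        skip_next <- TRUE
        next
      }
    }
    keep[i] <- TRUE
    n_acc <- n_acc + 1L
    accepted[n_acc] <- iv[i]
  }
  out <- record
  out$beats <- record$beats[keep, ]
  out
}

#' Test the minimum-data inclusion criterion
#'
#' A record enters the analysis only if it still contains at least
#' `min_normal` normal beats after ectopy filtering, so that enough N-N
#' data remain for windowing and feature extraction.
#'
#' @inheritParams filter_ectopic_beats
#' @param min_normal Minimum surviving N-beat count (default 1700).
#' @return `TRUE` or `FALSE`.
#' @export
check_inclusion <- function(record, min_normal = 1700L) {
  nrow(filter_ectopic_beats(record)$beats) >= min_normal
}

#' Extract the pre-event analysis window from a filtered record
#'
#' The warning horizon determines how close to the (potential) event the
#' analysed data may reach: intervals whose cumulative end-time falls
#' within the final `horizon` (300 s or 10 s) of the record's last beat
#' time are dropped, and the last `m` remaining intervals are returned in
#' order. Non-anchored (regular) records receive the identical trim
#' relative to their record end so both classes are processed the same
#' way. Cumulative time is the interval end-time convention: `t_j =
#' sum(interval_1..j)`.
#'
#' @param record A filtered [rr_record] (or one whose remaining beats are
#'   all to be used).
#' @param horizon `"five_minute"` (300 s trim) or `"ten_second"` (10 s).
#' @param m Window length in beats; defaults to 1000 for the five-minute
#'   horizon and 1600 for the ten-second horizon.
#' @return A numeric vector of exactly `m` intervals (seconds).
#' @export
extract_pre_event_window <- function(record,
                                     horizon = c("five_minute", "ten_second"),
                                     m = NULL) {
  horizon <- match.arg(horizon)
  m <- if (is.null(m)) default_window_m(horizon) else as.integer(m)
  iv <- if (is_rr_record(record)) record$beats$interval else as.numeric(record)
  t_end <- sum(iv)
  trim_s <- horizon_seconds(horizon)
  tj <- cumsum(iv)
  keep <- tj <= t_end - trim_s
  remaining <- iv[keep]
  if (length(remaining) < m) {
    stop(sprintf("window too short: %d intervals remain after the %s trim, need %d",
                 length(remaining), horizon, m), call. = FALSE)
  }
  utils::tail(remaining, m)
}

horizon_seconds <- function(horizon) {
  switch(horizon, five_minute = 300, ten_second = 10)
}

#' @rdname extract_pre_event_window
#' @export
default_window_m <- function(horizon = c("five_minute", "ten_second")) {
  switch(match.arg(horizon), five_minute = 1000L, ten_second = 1600L)
}

#' Filter, apply inclusion, and window a whole cohort
#'
#' Convenience verb running [filter_ectopic_beats()], [check_inclusion()]
#' and [extract_pre_event_window()] over a cohort tibble. Records that
#' fail inclusion or whose window is too short are dropped; the exclusion
#' log (one row per excluded record with a machine-readable reason code)
#' is attached as the `"exclusions"` attribute.
#'
#' @param cohort A cohort tibble (see [cohort_tbl]).
#' @inheritParams extract_pre_event_window
#' @param min_normal Minimum surviving N-beat count (default 1700).
#' @return A tibble with columns `patient_id`, `record_id`, `label`
#'   (rhythm class) and list-column `window` of m-interval vectors.
#' @export
window_cohort <- function(cohort, horizon = c("five_minute", "ten_second"),
                          m = NULL, min_normal = 1700L) {
  horizon <- match.arg(horizon)
  m <- if (is.null(m)) default_window_m(horizon) else as.integer(m)
  windows <- vector("list", nrow(cohort))
  reason <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    filtered <- filter_ectopic_beats(cohort$record[[i]])
    if (nrow(filtered$beats) < min_normal) {
      reason[i] <- "below_min_normal_beats"
      next
    }
    w <- tryCatch(extract_pre_event_window(filtered, horizon, m),
                  error = function(e) NULL)
    if (is.null(w)) {
      reason[i] <- "window_too_short"
      next
    }
    windows[[i]] <- w
  }
  ok <- !nzchar(reason)
  out <- tibble::tibble(
    patient_id = cohort$patient_id[ok],
    record_id = cohort$record_id[ok],
    label = cohort$rhythm_class[ok],
    window = windows[ok]
  )
  attr(out, "exclusions") <- tibble::tibble(
    record_id = cohort$record_id[!ok],
    reason = reason[!ok]
  )
  attr(out, "horizon") <- horizon
  attr(out, "window_m") <- m
  out
}
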