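#' Annotated R-R interval records
#'
#' An `rr_record` is an ordered tachogram: the sequence of R-R intervals
#' stored by an implantable device buffer (up to 2048 intervals), each beat
#' annotated as normal (`"N"`), premature ventricular / ectopic (`"V"`) or
#' compensatory pause (`"P"`), together with patient and rhythm-class
#' metadata. `rhythm_class` is `"regular"` for routine downloads and
#' `"pre_appropriate_shock"` for buffers whose final beat immediately
#' precedes an adjudicated appropriate shock; the latter are always
#' event-anchored.
#'
#' @param intervals Numeric vector of beat-to-beat intervals in seconds;
#'   each must lie strictly inside (0, 4) s.
#' @param labels Character vector of beat annotations, one of `"N"`, `"V"`,
#'   `"P"`; recycled if length 1.
#' @param patient_id,record_id Non-empty identifier strings.
#' @param rhythm_class `"regular"` or `"pre_appropriate_shock"`.
#' @param event_anchored Logical; `TRUE` when the record ends at the event.
#'   Defaults to `TRUE` for pre-appropriate-shock records (and must be
#'   `TRUE` for them).
#'
#' @return An object of class `rr_record`: a list with fields
#'   `patient_id`, `record_id`, `rhythm_class`, `event_anchored` and
#'   `beats`, a tibble with columns `interval` (s) and `label`.
#' @export
#' @examples
#' r <- rr_record(c(0.8, 0.79, 0.81), "N", "p1", "p1-r1", "regular")
#' n_beats(r)
rr_record <- function(intervals, labels, patient_id, record_id,
                      rhythm_class = c("regular", "pre_appropriate_shock"),
                      event_anchored = NULL) {
  rhythm_class <- match.arg(rhythm_class)
  if (length(labels) == 1L) labels <- rep(labels, length(intervals))
  if (length(labels) != length(intervals)) {
    stop("`intervals` and `labels` must have equal length", call. = FALSE)
  }
  if (is.null(event_anchored)) {
    event_anchored <- rhythm_class == "pre_appropriate_shock"
  }
  out <- structure(
    list(
      patient_id = as.character(patient_id),
      record_id = as.character(record_id),
      rhythm_class = rhythm_class,
      event_anchored = isTRUE(event_anchored),
      beats = tibble::tibble(interval = as.numeric(intervals),
                             label = as.character(labels))
    ),
    class = "rr_record"
  )
  validate_rr_record(out)
}

#' @rdname rr_record
#' @param x,record An `rr_record`.
#' @export
is_rr_record <- function(x) inherits(x, "rr_record")

validate_rr_record <- function(record) {
  if (!nzchar(record$patient_id)) stop("patient_id must be non-empty", call. = FALSE)
  if (!nzchar(record$record_id)) stop("record_id must be non-empty", call. = FALSE)
  b <- record$beats
  if (nrow(b) > 2048L) {
    stop("record exceeds the 2048-interval device buffer", call. = FALSE)
  }
  bad <- which(!is.finite(b$interval) | b$interval <= 0 | b$interval >= 4)
  if (length(bad)) {
    stop(sprintf("interval out of range (0, 4) s at beat %d", bad[1]), call. = FALSE)
  }
  badlab <- which(!b$label %in% c("N", "V", "P"))
  if (length(badlab)) {
    stop(sprintf("unknown beat label '%s' at beat %d", b$label[badlab[1]], badlab[1]),
         call. = FALSE)
  }
  if (record$rhythm_class == "pre_appropriate_shock" && !record$event_anchored) {
    stop("pre_appropriate_shock records must be event-anchored", call. = FALSE)
  }
  record
}

#' @rdname rr_record
#' @export
n_beats <- function(record) nrow(record$beats)

#' @export
print.rr_record <- function(x, ...) {
  cat(sprintf("<rr_record %s> patient %s, %s%s, %d beats (%d N)\n",
              x$record_id, x$patient_id, x$rhythm_class,
              if (x$event_anchored) ", event-anchored" else "",
              nrow(x$beats), sum(x$beats$label == "N")))
  invisible(x)
}

#' Read or write an annotated R-R record file
#'
#' The on-disk dialect is UTF-8 text: three header lines
#' `# patient_id: ...`, `# record_id: ...`, `# rhythm_class: ...`
#' (and optionally `# event_anchored: ...`), then one
#' `interval_ms<TAB>label` line per beat, intervals stored as integer
#' milliseconds. The round trip `read_rr_file(write_rr_file(r))` is the
#' identity at 1 ms resolution.
#'
#' @param path File path.
#' @return `read_rr_file()` returns an [rr_record] with intervals in
#'   seconds; `write_rr_file()` returns `path` invisibly.
#' @export
read_rr_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_header <- grepl("^#", lines)
  header <- lines[is_header]
  body <- lines[!is_header & nzchar(trimws(lines))]
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  for (key in c("patient_id", "record_id", "rhythm_class")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("%s: missing '%s' header", path, key), call. = FALSE)
    }
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- which(nfield != 2L)[1]
    stop(sprintf("%s: malformed line %d (expected 'interval_ms<TAB>label')",
                 path, which(!is_header & nzchar(trimws(lines)))[bad]), call. = FALSE)
  }
  ms <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  lab <- vapply(parts, `[[`, "", 2L)
  if (anyNA(ms)) {
    stop(sprintf("%s: non-numeric interval on body line %d", path, which(is.na(ms))[1]),
         call. = FALSE)
  }
  if (any(ms <= 0 | ms >= 4000)) {
    stop(sprintf("%s: interval out of range (0, 4000) ms on body line %d",
                 path, which(ms <= 0 | ms >= 4000)[1]), call. = FALSE)
  }
  anchored <- if (!is.null(meta$event_anchored)) {
    tolower(meta$event_anchored) %in% c("true", "yes", "1")
  } else NULL
  rr_record(ms / 1000, lab, meta$patient_id, meta$record_id,
            rhythm_class = meta$rhythm_class, event_anchored = anchored)
}

#' @rdname read_rr_file
#' @param record An [rr_record].
#' @export
write_rr_file <- function(record, path) {
  stopifnot(is_rr_record(record))
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(c(
    sprintf("# patient_id: %s", record$patient_id),
    sprintf("# record_id: %s", record$record_id),
    sprintf("# rhythm_class: %s", record$rhythm_class),
    sprintf("# event_anchored: %s", tolower(record$event_anchored)),
    sprintf("%d\t%s", as.integer(round(record$beats$interval * 1000)),
            record$beats$label)
  ), con)
  invisible(path)
}

#' Collect records into a cohort tibble
#'
#' A cohort is represented as a tibble with one row per record: metadata
#' columns `patient_id`, `record_id`, `rhythm_class`, `event_anchored`,
#' `n_beats`, `n_normal`, and a list-column `record` holding the
#' [rr_record] objects. The `provenance` attribute carries a free-text
#' origin note (synthetic seed or file manifest).
#'
#' @param records A list of [rr_record] objects.
#' @param provenance Free-text provenance string.
#' @return A cohort tibble.
#' @export
cohort_tbl <- function(records, provenance = "unspecified") {
  stopifnot(all(vapply(records, is_rr_record, logical(1))))
  ids <- vapply(records, `[[`, "", "record_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record_id '%s'", ids[anyDuplicated(ids)]), call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = vapply(records, `[[`, "", "patient_id"),
    record_id = ids,
    rhythm_class = vapply(records, `[[`, "", "rhythm_class"),
    event_anchored = vapply(records, `[[`, NA, "event_anchored"),
    n_beats = vapply(records, n_beats, integer(1)),
    n_normal = vapply(records, function(r) sum(r$beats$label == "N"), integer(1)),
    record = records
  )
  attr(out, "provenance") <- provenance
  out
}

#' Read a cohort from a directory or manifest
#'
#' @param path A directory containing `.rr` record files (scanned
#'   non-recursively) or a manifest text file listing one record-file path
#'   per line (relative paths resolved against the manifest's directory).
#' @return A cohort tibble (see [cohort_tbl]).
#' @export
read_cohort <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.rr$", full.names = TRUE)
    prov <- sprintf("directory %s", path)
  } else if (file.exists(path)) {
    files <- readLines(path)
    files <- files[nzchar(trimws(files))]
    rel <- !grepl("^(/|[A-Za-z]:)", files)
    files[rel] <- file.path(dirname(path), files[rel])
    prov <- sprintf("manifest %s", path)
  } else {
    stop(sprintf("no such cohort directory or manifest: %s", path), call. = FALSE)
  }
  if (!length(files)) stop("cohort is empty", call. = FALSE)
  cohort_tbl(lapply(files, read_rr_file), provenance = prov)
}

#' Write a cohort to a directory of record files plus a manifest
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fnames <- sprintf("%s.rr", cohort$record_id)
  purrr::walk2(cohort$record, file.path(dir, fnames), write_rr_file)
  manifest <- file.path(dir, "manifest.txt")
  writeLines(fnames, manifest)
  invisible(manifest)
}
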