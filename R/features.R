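#' Mean N-N interval of a window
#'
#' @param window Numeric vector of N-N intervals in seconds.
#' @return Arithmetic mean interval in seconds.
#' @export
mean_nn_interval <- function(window) {
  if (!length(window)) stop("empty window", call. = FALSE)
  mean(as.numeric(window))
}

# population (1/N) variance; the package-wide variance convention
var_pop <- function(x) mean((x - mean(x))^2)

#' Hjorth parameters of a tachogram window
#'
#' Time-domain descriptors of a signal computed from variance ratios of
#' successive differences over beat index: activity is the signal power
#' `var(y)`; mobility, an estimate of the mean (angular) frequency, is
#' `sqrt(var(diff(y)) / var(y))`; complexity, an estimate of bandwidth, is
#' the mobility of the first difference divided by the mobility of the
#' signal. Differences are taken per beat index (so mobility and
#' complexity are dimensionless) and variances are population (1/N)
#' variances of the full sequence available at each differencing level.
#'
#' @param window Numeric vector of intervals (length >= 3, non-constant).
#' @return A named list with `activity` (s^2), `mobility`, `complexity`.
#' @export
hjorth_parameters <- function(window) {
  y <- as.numeric(window)
  if (length(y) < 3L) stop("need at least 3 samples", call. = FALSE)
  d1 <- diff(y)
  d2 <- diff(d1)
  v0 <- var_pop(y)
  v1 <- var_pop(d1)
  v2 <- var_pop(d2)
  if (v0 <= 0 || v1 <= 0) stop("degenerate (constant) signal", call. = FALSE)
  mob <- sqrt(v1 / v0)
  list(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' Detrended fluctuation analysis scaling exponents
#'
#' DFA quantifies the self-similarity of a (possibly non-stationary)
#' series: the mean-centered series is integrated, partitioned into
#' non-overlapping boxes of `n` beats, each box is detrended by a
#' least-squares line, and `F(n)` is the root-mean-square residual. The
#' short-term exponent `alpha1` is the ordinary-least-squares slope of
#' `log10 F(n)` versus `log10 n` over box sizes 4-16 beats and the
#' long-term exponent `alpha2` over 16-64 beats (all integer sizes;
#' the standard box ranges for beat-indexed heart-rate series). White
#' noise gives alpha ~ 0.5, 1/f noise ~ 1.0, Brownian noise ~ 1.5.
#'
#' @param window Numeric vector of intervals, length >= 128.
#' @param short_range,long_range Integer box-size ranges for the two
#'   exponents.
#' @return A named list with `alpha1` and `alpha2`.
#' @export
dfa_exponents <- function(window, short_range = 4:16, long_range = 16:64) {
  x <- as.numeric(window)
  if (length(x) < 128L) stop("DFA needs at least 128 intervals", call. = FALSE)
  y <- cumsum(x - mean(x))
  sizes <- sort(unique(c(short_range, long_range)))
  fn <- vapply(sizes, dfa_fluctuation, numeric(1), y = y)
  fit_slope <- function(rng) {
    sel <- sizes %in% rng
    lx <- log10(sizes[sel])
    ly <- log10(fn[sel])
    sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  }
  list(alpha1 = fit_slope(short_range), alpha2 = fit_slope(long_range))
}

# RMS residual of per-box linear detrending at one box size
dfa_fluctuation <- function(y, n) {
  nb <- length(y) %/% n
  ym <- matrix(y[seq_len(nb * n)], nrow = n)
  x <- seq_len(n)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slopes <- colSums(ym * xc) / sxx
  centered <- sweep(ym, 2, colMeans(ym))
  rss <- colSums(centered^2) - slopes^2 * sxx
  sqrt(sum(pmax(rss, 0)) / (nb * n))
}

#' Extract the scalar HRV feature row for one window
#'
#' Computes the ten scalar predictors used by the warning classifiers:
#' mean N-N interval, Hjorth mobility and complexity, the DFA exponents
#' `alpha1` and `alpha2`, and the Lomb-periodogram power in five
#' logarithmic frequency bins (`bp1`..`bp5`, low to high frequency).
#' Principal-component coefficients are appended later, per training set,
#' by [project_record()] inside the evaluation loop.
#'
#' @param window Numeric vector of m intervals (seconds).
#' @param patient_id,record_id,label Metadata carried into the row.
#' @return A one-row tibble with the metadata and the ten features.
#' @export
extract_feature_row <- function(window, patient_id = NA_character_,
                                record_id = NA_character_,
                                label = NA_character_) {
  ctx <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("record %s: %s", record_id, conditionMessage(e)), call. = FALSE)
    })
  }
  hj <- ctx(hjorth_parameters(window))
  dfa <- ctx(dfa_exponents(window))
  bp <- ctx(log_band_powers(window))
  tibble::tibble(
    patient_id = patient_id, record_id = record_id, label = label,
    mean_nn = mean_nn_interval(window),
    mobility = hj$mobility, complexity = hj$complexity,
    alpha1 = dfa$alpha1, alpha2 = dfa$alpha2,
    bp1 = bp$power[1], bp2 = bp$power[2], bp3 = bp$power[3],
    bp4 = bp$power[4], bp5 = bp$power[5]
  )
}

#' Extract scalar features for every window in a windowed cohort
#'
#' @param windowed A tibble from [window_cohort()] (columns `patient_id`,
#'   `record_id`, `label`, list-column `window`).
#' @return A tibble with one feature row per record; the `window`
#'   list-column is retained so the evaluation loop can refit PCA per
#'   training set.
#' @export
extract_features <- function(windowed) {
  rows <- purrr::pmap(
    list(windowed$window, windowed$patient_id, windowed$record_id, windowed$label),
    function(w, p, r, l) extract_feature_row(w, p, r, l)
  )
  out <- dplyr::bind_rows(rows)
  out$window <- windowed$window
  attr(out, "horizon") <- attr(windowed, "horizon")
  attr(out, "window_m") <- attr(windowed, "window_m")
  out
}

#' @rdname extract_features
#' @export
scalar_feature_names <- function() {
  c("alpha1", "alpha2", "mean_nn", paste0("bp", 1:5), "complexity", "mobility")
}
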