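#' Per-class generative parameters for synthetic tachograms
#'
#' A `synth_class_spec` bundles the statistical knobs of the per-class
#' tachogram generator:
#'
#' * `mean_nn_median`, `mean_nn_iqr`: target median and IQR (s) of the
#'   per-record mean N-N interval; the per-record level `mu` is drawn from
#'   the log-normal matched in closed form to these quantiles;
#' * `gamma`: power-law spectral exponent of the beat-indexed fluctuation
#'   (spectrum ~ 1/f^gamma over cycles/beat), related to the DFA exponent
#'   by `alpha = (gamma + 1) / 2`; `gamma_sd` is the between-record jitter
#'   that produces the population spread of the scaling exponents;
#' * `rolloff`: optional low-pass knee `list(fc, q)` multiplying the
#'   power-law amplitude by `(1 + (f/fc)^q)^(-1/2)`, reproducing the steep
#'   high-frequency decay of sinus-rhythm tachograms (without it the
#'   power law extends to the Nyquist frequency, the configuration used
#'   for estimator-recovery checks); `highpass` is the matching
#'   low-frequency knee `(1 + (fc/f)^q)^(-1/2)` that concentrates power in
#'   the very-low/low-frequency band, as in the reference spectra;
#' * `hf_fraction`: fraction of fluctuation variance placed in a
#'   broadband noise floor above `hf_lo` cycles/beat (default 0.15);
#'   `hf_logit_sd` its between-record jitter on the logit scale;
#' * `knee_sdlog`: log-normal per-record jitter applied jointly to both
#'   knee frequencies, shifting the whole spectral band up or down and
#'   producing the wide population spread of Hjorth mobility and band
#'   powers seen in the reference tables;
#' * `fluctuation_sd_scale`: median fluctuation SD (s); `scale_sdlog`
#'   log-normal between-record jitter producing the band-power spread;
#' * `trend_slope_mean`, `trend_slope_sd`: per-record linear trend (s per
#'   beat), centered within the record;
#' * `ectopy_rate`: per-beat probability of an injected ectopic pair;
#' * `surge`: optional near-event surge, applied only to event-anchored
#'   records: an exponentially weighted ramp `w_i = exp((i - n) / tau)`
#'   adds high-frequency variability (`hf_sd`, s) and shortens the mean
#'   interval (`drop`, s) over roughly the final `tau` beats, emulating
#'   the intensifying autonomic disturbance immediately before
#'   tachyarrhythmia onset.
#'
#' @param label Class label.
#' @param mean_nn_median,mean_nn_iqr Log-normal quantile targets (s).
#' @param gamma,gamma_sd Spectral exponent and its per-record jitter.
#' @param hf_fraction,hf_logit_sd High-frequency variance fraction and
#'   its logit-scale jitter.
#' @param hf_lo Lower edge (cycles/beat) of the noise-floor band.
#' @param rolloff,highpass `NULL` or `list(fc = cycles/beat, q =
#'   steepness)`: low-pass / high-pass spectral knees.
#' @param knee_sdlog Per-record log-normal jitter of the knee frequencies.
#' @param fluctuation_sd_scale,scale_sdlog Fluctuation SD (s) and its
#'   log-normal jitter.
#' @param trend_slope_mean,trend_slope_sd Linear trend distribution
#'   (s/beat).
#' @param ectopy_rate Per-beat ectopic-pair probability, in \[0, 0.2).
#' @param surge `NULL` or `list(tau = beats, hf_sd = s, drop = s)`.
#' @return A list of class `synth_class_spec`.
#' @export
synth_class_spec <- function(label, mean_nn_median, mean_nn_iqr,
                             gamma, gamma_sd = 0,
                             hf_fraction = 0, hf_logit_sd = 0, hf_lo = 0.15,
                             rolloff = NULL, highpass = NULL, knee_sdlog = 0,
                             fluctuation_sd_scale = 0.05, scale_sdlog = 0,
                             trend_slope_mean = 0, trend_slope_sd = 0,
                             ectopy_rate = 0, surge = NULL) {
  stopifnot(mean_nn_median > 0, hf_fraction >= 0, hf_fraction <= 1,
            ectopy_rate >= 0, ectopy_rate < 0.2,
            length(mean_nn_iqr) == 2, mean_nn_iqr[1] < mean_nn_iqr[2])
  structure(
    list(label = label, mean_nn_median = mean_nn_median,
         mean_nn_iqr = mean_nn_iqr, gamma = gamma, gamma_sd = gamma_sd,
         hf_fraction = hf_fraction, hf_logit_sd = hf_logit_sd, hf_lo = hf_lo,
         rolloff = rolloff, highpass = highpass, knee_sdlog = knee_sdlog,
         fluctuation_sd_scale = fluctuation_sd_scale, scale_sdlog = scale_sdlog,
         trend_slope_mean = trend_slope_mean, trend_slope_sd = trend_slope_sd,
         ectopy_rate = ectopy_rate, surge = surge),
    class = "synth_class_spec"
  )
}

#' Default class specifications calibrated to the published group tables
#'
#' The regular class targets the published regular-rhythm marginals
#' (median mean N-N 0.802 s, alpha2 1.03 hence gamma = 2 x 1.03 - 1 =
#' 1.06, low Hjorth mobility ~ 0.076, small positive rate trend); the
#' pre-shock class targets the pre-appropriate-shock marginals (median
#' mean N-N 0.694 s, alpha2 0.644 hence gamma = 0.29, high mobility,
#' plus a near-event surge that reproduces the stronger deviations seen
#' in the 10-second window: mobility rising to ~ 0.2 and the mean N-N
#' interval shortening as the event approaches). The dispersion knobs
#' (gamma_sd, hf_logit_sd, scale_sdlog) were tuned once, against the
#' published IQRs, with the tuning script shipped in `tools/`.
#'
#' @return A named list with elements `regular` and `pre_appropriate_shock`.
#' @export
default_class_specs <- function() {
  list(
    regular = synth_class_spec(
      label = "regular",
      mean_nn_median = 0.802, mean_nn_iqr = c(0.716, 0.902),
      gamma = 1.06, gamma_sd = 0.5,
      rolloff = list(fc = 0.022, q = 4), highpass = list(fc = 0.009, q = 2),
      knee_sdlog = 0.6,
      hf_fraction = 0, hf_logit_sd = 0,
      fluctuation_sd_scale = 0.055, scale_sdlog = 0.65,
      trend_slope_mean = 5e-6, trend_slope_sd = 2e-5,
      ectopy_rate = 0.01
    ),
    pre_appropriate_shock = synth_class_spec(
      label = "pre_appropriate_shock",
      mean_nn_median = 0.694, mean_nn_iqr = c(0.583, 0.804),
      gamma = 0.29, gamma_sd = 0.5,
      rolloff = list(fc = 0.035, q = 4), highpass = list(fc = 0.025, q = 2),
      knee_sdlog = 0.6,
      hf_fraction = 0.01, hf_logit_sd = 0.9,
      fluctuation_sd_scale = 0.04, scale_sdlog = 0.65,
      trend_slope_mean = -5e-6, trend_slope_sd = 2e-5,
      ectopy_rate = 0.09,
      surge = list(tau = 100, hf_sd = 0.02, drop = 0.05)
    )
  )
}

# unit-variance random-phase series with amplitude spectrum amp(f),
# f in cycles/beat
random_phase_series <- function(n, amp) {
  nf <- n %/% 2
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(modulus = amp[nf], argument = 0)
    if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[n:(n - nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- sqrt(mean((x - mean(x))^2))
  (x - mean(x)) / s
}

# power-law synthesis: amplitude ~ f^(-gamma/2), optionally low-passed by a
# knee (1 + (f/fc)^q)^(-1/2) emulating the steep high-frequency decay of
# sinus-rhythm tachograms
powerlaw_series <- function(n, gamma, rolloff = NULL, highpass = NULL) {
  f <- (1:(n %/% 2)) / n
  amp <- f^(-gamma / 2)
  if (!is.null(rolloff)) {
    amp <- amp / sqrt(1 + (f / rolloff$fc)^rolloff$q)
  }
  if (!is.null(highpass)) {
    amp <- amp / sqrt(1 + (highpass$fc / f)^highpass$q)
  }
  random_phase_series(n, amp)
}

# unit-variance noise floor: flat spectrum above f_lo cycles/beat
hf_series <- function(n, f_lo = 0.15) {
  f <- (1:(n %/% 2)) / n
  random_phase_series(n, as.numeric(f > f_lo))
}

#' Generate one synthetic tachogram
#'
#' Draws the per-record level from the class's log-normal, synthesises
#' beat-indexed fluctuations as a mixture of a power-law (1/f^gamma)
#' component and a high-frequency component, adds a (record-centered)
#' linear trend and, for event-anchored records, the near-event surge,
#' then clips intervals to the physiological range \[0.3, 2.0\] s. All
#' beats are labelled `"N"`; ectopy is injected separately by
#' [inject_ectopy()]. Uses the current RNG state (seed upstream for
#' reproducibility).
#'
#' @param spec A [synth_class_spec].
#' @param n_beats Number of beats (>= 256).
#' @param patient_id,record_id Metadata for the resulting record.
#' @param event_anchored Whether the record ends at an event (enables the
#'   surge term and marks the record pre-appropriate-shock).
#' @return An [rr_record].
#' @export
generate_tachogram <- function(spec, n_beats = 2048L,
                               patient_id = "synthetic", record_id = "synthetic-1",
                               event_anchored = spec$label == "pre_appropriate_shock") {
  stopifnot(inherits(spec, "synth_class_spec"), n_beats >= 256L)
  n <- as.integer(n_beats)
  sdlog <- log(spec$mean_nn_iqr[2] / spec$mean_nn_iqr[1]) / (2 * stats::qnorm(0.75))
  mu <- stats::rlnorm(1, meanlog = log(spec$mean_nn_median), sdlog = sdlog)
  gamma_i <- min(3, max(-1, stats::rnorm(1, spec$gamma, spec$gamma_sd)))
  hf_i <- if (spec$hf_fraction > 0) {
    stats::plogis(stats::qlogis(spec$hf_fraction) + stats::rnorm(1, 0, spec$hf_logit_sd))
  } else 0
  sd_i <- spec$fluctuation_sd_scale * exp(stats::rnorm(1, 0, spec$scale_sdlog))
  rolloff_i <- spec$rolloff
  highpass_i <- spec$highpass
  if (spec$knee_sdlog > 0) {
    shift <- exp(stats::rnorm(1, 0, spec$knee_sdlog))
    if (!is.null(rolloff_i)) rolloff_i$fc <- rolloff_i$fc * shift
    if (!is.null(highpass_i)) highpass_i$fc <- highpass_i$fc * shift
  }
  fluct <- sqrt(1 - hf_i) *
    powerlaw_series(n, gamma_i, rolloff_i, highpass_i)
  if (hf_i > 0) fluct <- fluct + sqrt(hf_i) * hf_series(n, spec$hf_lo)
  fluct <- sd_i * fluct
  slope <- stats::rnorm(1, spec$trend_slope_mean, spec$trend_slope_sd)
  idx <- seq_len(n)
  rr <- mu + slope * (idx - (n + 1) / 2) + fluct
  if (event_anchored && !is.null(spec$surge)) {
    w <- exp((idx - n) / spec$surge$tau)
    rr <- rr + spec$surge$hf_sd * sqrt(w) * hf_series(n, spec$hf_lo) -
      spec$surge$drop * w
  }
  clipped <- rr < 0.3 | rr > 2.0
  if (mean(clipped) > 0.5) {
    stop("degenerate generator parameters: more than 50% of intervals clipped",
         call. = FALSE)
  }
  rr <- pmin(pmax(rr, 0.3), 2.0)
  cls <- if (event_anchored) "pre_appropriate_shock" else "regular"
  rr_record(rr, "N", patient_id, record_id, rhythm_class = cls,
            event_anchored = event_anchored)
}

#' Inject ectopic beat / compensatory pause pairs
#'
#' At each selected position the interval `RR` is replaced by the pair
#' (`0.6 RR` labelled `"V"`, `1.4 RR` labelled `"P"`), preserving the
#' summed duration (0.6 + 1.4 = 2.0x) so cumulative time stays
#' physiological. Selected positions are never adjacent, so pairs never
#' overlap. Uses the current RNG state.
#'
#' @param record An [rr_record].
#' @param rate Per-beat selection probability in \[0, 0.2).
#' @return An [rr_record] with `n + n_events` beats.
#' @export
inject_ectopy <- function(record, rate) {
  stopifnot(is_rr_record(record))
  if (rate < 0 || rate >= 0.2) stop("ectopy rate must lie in [0, 0.2)", call. = FALSE)
  if (rate == 0) return(record)
  iv <- record$beats$interval
  lab <- record$beats$label
  n <- length(iv)
  pos <- which(stats::runif(n) < rate & lab == "N")
  if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) > 1L)]
  if (!length(pos)) return(record)
  reps <- rep(1L, n)
  reps[pos] <- 2L
  newiv <- rep(iv, reps)
  newlab <- rep(lab, reps)
  first <- cumsum(reps) - reps + 1L
  newiv[first[pos]] <- 0.6 * iv[pos]
  newlab[first[pos]] <- "V"
  newiv[first[pos] + 1L] <- 1.4 * iv[pos]
  newlab[first[pos] + 1L] <- "P"
  out <- record
  # beat count grows by one per injected pair and may transiently exceed
  # the device buffer; generate_cohort() truncates to the most recent
  # n_beats afterwards, mirroring a rolling buffer
  out$beats <- tibble::tibble(interval = newiv, label = newlab)
  out
}

#' Cohort-level generator specification
#'
#' @param n_regular,n_preshock Record counts per class (study design:
#'   6660 and 230).
#' @param records_per_patient_mean Mean regular records per patient
#'   (Poisson, truncated at 1; study value 8.5).
#' @param n_beats Beats per record, at most the 2048-interval device
#'   buffer (default 2048).
#' @param seed Integer master seed; the cohort is fully reproducible.
#' @param class_specs Named list from [default_class_specs()] (or
#'   modified copies).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regular = 6660L, n_preshock = 230L,
                        records_per_patient_mean = 8.5,
                        n_beats = 2048L, seed = 1L,
                        class_specs = default_class_specs()) {
  stopifnot(n_regular >= 1L, n_preshock >= 1L, n_beats <= 2048L,
            n_beats >= 256L)
  structure(
    list(n_regular = as.integer(n_regular), n_preshock = as.integer(n_preshock),
         records_per_patient_mean = records_per_patient_mean,
         n_beats = as.integer(n_beats), seed = as.integer(seed),
         class_specs = class_specs),
    class = "cohort_spec"
  )
}

#' Generate a two-class synthetic cohort
#'
#' Regular records are distributed over patients with a truncated-Poisson
#' number of records per patient (mean `records_per_patient_mean`, >= 1);
#' pre-shock records are event-anchored and assigned to randomly chosen
#' patients. After optional ectopy injection each record is truncated to
#' its most recent `n_beats` intervals, mirroring a rolling device
#' buffer. The result is byte-reproducible from the seed.
#'
#' @param cspec A [cohort_spec].
#' @return A cohort tibble (see [cohort_tbl]) with provenance
#'   `"synthetic seed <seed>"`.
#' @export
generate_cohort <- function(cspec = cohort_spec()) {
  stopifnot(inherits(cspec, "cohort_spec"))
  set.seed(cspec$seed)
  n_pat <- max(1L, ceiling(cspec$n_regular / cspec$records_per_patient_mean))
  per_pat <- pmax(1L, stats::rpois(n_pat, cspec$records_per_patient_mean))
  while (sum(per_pat) < cspec$n_regular) {
    per_pat <- c(per_pat, max(1L, stats::rpois(1, cspec$records_per_patient_mean)))
  }
  reg_patients <- rep(sprintf("P%04d", seq_along(per_pat)), per_pat)[seq_len(cspec$n_regular)]
  pre_patients <- sample(unique(reg_patients), cspec$n_preshock, replace = TRUE)

  make_one <- function(spec, pid, rid, anchored) {
    # an extreme joint draw of level and fluctuation scale can clip more
    # than half the record; redraw rather than abort the whole cohort
    for (attempt in 1:20) {
      r <- tryCatch(
        generate_tachogram(spec, cspec$n_beats, pid, rid, event_anchored = anchored),
        error = function(e) if (grepl("clipped", conditionMessage(e))) NULL else stop(e)
      )
      if (!is.null(r)) break
    }
    if (is.null(r)) stop("generator produced only degenerate records", call. = FALSE)
    if (spec$ectopy_rate > 0) r <- inject_ectopy(r, spec$ectopy_rate)
    if (nrow(r$beats) > cspec$n_beats) {
      r$beats <- utils::tail(r$beats, cspec$n_beats)
    }
    r
  }
  reg_spec <- cspec$class_specs$regular
  pre_spec <- cspec$class_specs$pre_appropriate_shock
  records <- c(
    lapply(seq_len(cspec$n_regular), function(i) {
      make_one(reg_spec, reg_patients[i], sprintf("R-%05d", i), FALSE)
    }),
    lapply(seq_len(cspec$n_preshock), function(i) {
      make_one(pre_spec, pre_patients[i], sprintf("S-%05d", i), TRUE)
    })
  )
  cohort_tbl(records, provenance = sprintf("synthetic seed %d", cspec$seed))
}

#' Compare synthetic feature marginals with the published reference
#'
#' Windows and featurizes the cohort at the given horizon, then tabulates
#' per feature and class the synthetic median and IQR side by side with
#' the published constants ([hrv_reference_stats()]), the relative
#' deviation of medians, and a flag. The flag criterion is a relative
#' median deviation above 25% for `mean_nn`, `mobility`, `complexity`,
#' `alpha1` and `alpha2`; band powers are compared in order of magnitude
#' only (flagged above one decade).
#'
#' @param cohort A cohort tibble.
#' @param horizon `"five_minute"` or `"ten_second"`.
#' @param m Window length override (defaults per horizon).
#' @return A tibble with one row per feature x class.
#' @export
calibration_report <- function(cohort, horizon = c("five_minute", "ten_second"),
                               m = NULL) {
  horizon <- match.arg(horizon)
  feats <- extract_features(window_cohort(cohort, horizon, m))
  ref <- hrv_reference_stats(horizon)
  syn <- feats |>
    tidyr::pivot_longer(dplyr::all_of(scalar_feature_names()),
                        names_to = "feature", values_to = "value") |>
    dplyr::group_by(.data$label, .data$feature) |>
    dplyr::summarise(
      synthetic_median = stats::median(.data$value),
      synthetic_iqr_lo = stats::quantile(.data$value, 0.25),
      synthetic_iqr_hi = stats::quantile(.data$value, 0.75),
      .groups = "drop") |>
    dplyr::rename(class = "label")
  out <- dplyr::left_join(ref, syn, by = c("feature", "class"))
  out$rel_deviation <- (out$synthetic_median - out$median) / out$median
  is_band <- grepl("^bp", out$feature)
  out$flag <- ifelse(
    is_band,
    abs(log10(out$synthetic_median / out$median)) > 1,
    abs(out$rel_deviation) > 0.25
  )
  out
}
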