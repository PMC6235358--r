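# fixtures are built in code; nothing is read from disk

steady_record <- function(n = 100, iv = 0.8, label = "N", patient = "p1",
                          id = "r1", class = "regular") {
  rr_record(rep(iv, n), label, patient, id, rhythm_class = class)
}

# steady record whose intervals encode their index (0.8 + j * 1e-6 s) so
# window extraction can be checked positionally
indexed_record <- function(n = 2048, base = 0.8) {
  rr_record(base + seq_len(n) * 1e-6, "N", "p1", "r1")
}

random_record <- function(n = 50, seed = 1, id = "r1") {
  set.seed(seed)
  iv <- round(runif(n, 0.4, 1.6), 3)  # 1 ms resolution for round trips
  labs <- sample(c("N", "V", "P"), n, replace = TRUE, prob = c(0.9, 0.05, 0.05))
  rr_record(iv, labs, "p1", id)
}

# tiny two-class feature cohort for classifier tests: class separation on
# one informative feature plus noise features
toy_features <- function(n_per_class = 40, seed = 1, delta = 3) {
  set.seed(seed)
  tibble::tibble(
    patient_id = rep(c("pa", "pb"), each = n_per_class),
    record_id = sprintf("t%03d", seq_len(2 * n_per_class)),
    label = rep(c("regular", "pre_appropriate_shock"), each = n_per_class),
    f1 = c(rnorm(n_per_class, 0), rnorm(n_per_class, delta)),
    f2 = rnorm(2 * n_per_class),
    f3 = rnorm(2 * n_per_class)
  )
}

# small synthetic cohort with short records for fast end-to-end tests
small_cohort <- function(n_reg = 50, n_pre = 50, n_beats = 1024, seed = 5) {
  generate_cohort(cohort_spec(n_regular = n_reg, n_preshock = n_pre,
                              n_beats = n_beats, seed = seed))
}

# windowed features at reduced window length for evaluation-loop tests
small_features <- function(cohort, horizon = "five_minute", m = 256) {
  extract_features(window_cohort(cohort, horizon, m = m, min_normal = 300L))
}
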