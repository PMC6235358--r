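# vtwarn

Heart-rate-variability (HRV) warning system for ventricular
tachyarrhythmia, built around the R-R interval buffers stored by
implantable cardioverter-defibrillators (ICDs).

ICDs terminate ventricular tachycardia / fibrillation (VT/VF) with
painful shocks after onset. A warning system instead asks: can the rhythm
*preceding* an appropriate shock be distinguished from the same patients'
routine ("regular") rhythms, five minutes or ten seconds before the
event? `vtwarn` implements the full analysis pipeline for that question,
for researchers working with beat-annotated tachograms:

- **Records** — an `rr_record` holds up to 2048 annotated R-R intervals
  (`N` normal, `V` premature ventricular, `P` compensatory pause) plus
  patient/rhythm metadata, with plain-text file I/O, ectopy cleaning (a
  label rule plus a 20% running-median timing rule), a 1700-normal-beat
  inclusion criterion, and pre-event windowing (the last `m` intervals
  after trimming the final 300 s or 10 s; `m` = 1000 or 1600).
- **Features** — per window: mean N-N interval; Hjorth mobility
  `sqrt(var(diff(y)) / var(y))` and complexity (bandwidth); detrended
  fluctuation analysis exponents `alpha1` (boxes 4–16 beats) and `alpha2`
  (16–64); and Lomb-periodogram power integrated over five
  log10-equispaced bins spanning `1/T`–0.5 Hz (the Lomb estimator handles
  the uneven sampling of a tachogram natively; compiled kernel).
- **Tachogram PCA** — windows are stacked as columns of an `m x n`
  matrix, centered by the mean profile, standardized per column, and
  decomposed as `R = U S V^T`; the retained rank is chosen by the
  Gavish–Donoho optimal hard threshold
  `tau* = omega(n/m) * median(singular values)`,
  `omega(b) = 0.56 b^3 - 0.95 b^2 + 1.82 b + 1.43`.
- **Evaluation** — repeated balanced resampling: undersample the majority
  class, split 80/20 stratified, refit the PCA on training windows only,
  train a random forest (500 trees, OOB permutation importances) and a
  linear SVM (cost 1, training-set normalization), and report mean (SD)
  sensitivity, specificity and AUC over trials, plus Mann–Whitney group
  tables.
- **Synthetic cohorts** — the original ICD study data are not public, so
  a calibrated generator produces two-class cohorts whose feature
  marginals are matched to the published group statistics (band-passed
  power-law spectra in the beat domain, log-normal mean N-N levels,
  injected ectopic pairs, and a pre-event autonomic surge). The whole
  pipeline is therefore reproducible from a seed.

## Worked example

```r
library(vtwarn)

cohort <- generate_cohort(cohort_spec(n_regular = 150, n_preshock = 150,
                                      seed = 42))
feats  <- extract_features(window_cohort(cohort, "five_minute"))
ev     <- run_evaluation(feats, eval_config(horizon = "five_minute",
                                            n_trials = 10, seed = 7,
                                            classifiers = "random_forest"))
ev
#> <vt_eval> five_minute horizon, 10 trials (0 failed)
#>      classifier mean_auc mean_sensitivity mean_specificity sd_auc ...
#> 1 random_forest    0.959            0.979            0.864 0.0143
```

The mean AUC (0.96 here) is the probability that a randomly chosen
pre-shock window outscores a randomly chosen regular window; sensitivity
and specificity are the balanced test-set hit rates at the forest's 0.5
vote threshold. Re-running with `horizon = "ten_second"` gives a higher
AUC (0.98 on this cohort) — the near-event window carries a stronger
signature, mirroring the ordering reported for the clinical data.
`autoplot(ev)` shows the per-trial metric distributions,
`plot_importance(ev)` the mean permutation importances in the standard
predictor ordering (PC 1..k, alpha1, alpha2, mean N-N, five band powers,
complexity, mobility), and `calibration_report(cohort, "five_minute")`
compares the synthetic feature marginals with the published reference
values feature by feature.

A thin command-line wrapper with `simulate` / `features` / `evaluate` /
`group-stats` subcommands ships in `inst/cli/vtwarn`.

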