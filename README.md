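# posturogaze

Oculo-postural coupling analysis for small clinical cohorts: does gaze
behaviour recorded during a natural task predict standing balance?

Early diffuse white-matter damage (for example radiation-induced
leukoencephalopathy after cerebral radiotherapy) degrades attention and
executive function before balance problems are clinically visible. Two
inexpensive recordings are sensitive to that stage: centre-of-pressure
(CoP) sway on a force platform during a Romberg test (25 s eyes open,
25 s eyes closed), and eye movements during an everyday task.
`posturogaze` implements the complete analysis chain between them, for
cohorts of ten-or-so patients where leave-one-out validation and
permutation importance are the only honest options.

## What it computes

**Postural score.** Irregularly sampled CoP recordings are resampled to
25 Hz by a sliding-window average with interpolation fallback (SWARII),
cut into 1 s windows over the final 25 s per condition, and each window is
classified *quiet* or *unquiet* by a two-component Gaussian mixture fitted
on windows pooled across the whole cohort. With unquiet fractions f_EO and
f_EC,

    score = 100 * ((1 - f_EO) + (1 - f_EC)) / 2        (0 bad ... 100 excellent)

**Oculomotor biomarkers.** A velocity-threshold (I-VT) classifier
(30 deg/s, 60 ms minimum fixation, 75 ms maximum bridgeable gap) segments
gaze into fixations and saccades; 18 biomarkers summarise per-second
ranges and variability, velocities, the 95% confidence-ellipse area, and
fixation/saccade duration statistics.

**Coupling.** A regression random forest (implemented in this package in
C++) predicts the postural score from the 18 biomarkers in patients only.
Feature importance follows the out-of-bag permutation statistic

    Imp_i = mean(d_i) / sd(d_i)

where d is the per-tree out-of-bag squared-error change after permuting
biomarker i, over the trees that used i. The procedure runs five times and
a biomarker is selected when the lower quartile of its five importances
exceeds 0.1. Prediction quality is leave-one-out normalised RMSE
(RMSE / 100), with and without the single worst residual.

**Cohort inference.** Wilcoxon rank-sum comparison of scores between
patients and controls (exact null for n <= 10 without ties) and Pearson
correlation of the score with an attention subscore (0-37).

**Synthetic cohorts.** A seeded generator plants a latent severity per
subject that jointly shortens fixations, widens gaze excursions
(calibrated endpoints: mean fixation 316 -> 153 ms, horizontal range
6.0 -> 14.6 deg/s as severity goes 0 -> 1) and raises the unquiet sway
fraction — so the whole pipeline is testable against planted truth, with
a null switch (`effect_scale = 0`) that severs the gaze-posture link.

## Worked example

```r
library(posturogaze)

cfg <- pipeline_config(
  cohort = cohort_config(n_patients = 10, n_controls = 9, seed = 42),
  out_dir = "demo_run", seed = 42)
res <- run_pipeline(cfg)
```

This simulates a 19-subject cohort, scores posture, extracts gaze
features, and models the patients. The run prints nothing; the results
live in `res` and in `demo_run/`:

```r
res$report$groups[, c("n", "median")]
#>         n  median
#> control 9      84
#> patient 10     53
signif(res$report$rank_sum$p_value, 3)
#> [1] 0.000275
res$selected
#> [1] "RangeX" "RangeY" "VarianceX" "VarianceY" "VelocityX" "VelocityY"
#> [7] "Velocity" "EllArea" "MeanFix" "VarianceFix" "MeanSac" "VarianceSac"
#> [13] "KurtSac" "Fix2SacNratio"
round(c(all = res$prediction_all$rmse_norm,
        selected = res$prediction_selected$rmse_norm,
        selected_excl = res$prediction_selected$rmse_norm_excl), 3)
#>           all      selected selected_excl
#>         0.054         0.050         0.031
```

Patients score well below controls (median 53 vs 84, rank-sum
p = 0.000275 — the planted severity gap), the dynamic gaze biomarkers are
selected as informative, and gaze predicts the postural score with a
leave-one-out normalised RMSE of 0.054 (0.050 after refitting on the
selected subset, 0.031 after excluding the worst-predicted subject).
`demo_run/` holds `scores.csv`, `features.csv`, `importance.csv`,
`predictions_*.csv`, `report.json` and `run_log.json`, each stamped with
the config hash; rerunning the same config reproduces them byte for byte.

A command-line interface with the same stages ships in
`exec/posturogaze` (`simulate`, `score-posture`, `extract-gaze`, `select`,
`predict`, `report`, `run-all`).

## Design notes

See the methods vignette (`vignettes/oculo-postural-coupling.Rmd`) for the
model assumptions, parameter defaults and units, what the synthetic
generator does and does not emulate, numerical conventions (quantile type,
kurtosis convention, degenerate-input handling), and known limitations.
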