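---
title: "Methods: quantifying oculo-postural coupling in small cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying oculo-postural coupling in small cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Diffuse white-matter damage — for example radiation-induced
leukoencephalopathy after cerebral radiotherapy — impairs attention and
executive function before any balance or gait deficit is clinically
detectable. Two cheap, non-invasive signals are sensitive to this early
stage: the sway of the centre of pressure (CoP) during quiet standing, and
eye movements recorded during a natural task. `posturogaze` implements the
full analysis chain that connects them:

1. a **0–100 postural score** from irregularly sampled CoP recordings
   (eyes open and eyes closed, 25 s each);
2. **eighteen oculomotor biomarkers** from gaze-angle traces;
3. a **predictive coupling analysis**: out-of-bag permutation importance
   from a random-forest regression, a quartile-threshold selection rule,
   and leave-one-out prediction of the postural score with normalised RMSE;
4. cohort-level inference (rank-sum group comparison, Pearson correlation
   with an attention subscore);
5. a **synthetic-cohort generator** so that every stage is testable without
   patient data.

# The postural score

Force platforms of the consumer class sample at a non-constant rate, so the
recording is first resampled to a uniform 25 Hz grid with a sliding-window
average: each grid value is the mean of the raw samples within a centred
window (default one target period, 0.04 s), falling back to linear
interpolation between the two nearest samples when the window is empty.
Both operations are convex combinations, so resampled values never leave
the range of the raw data.

Only the final 25 s of each condition are scored (the preceding portion is
acclimatisation). The signal is cut into consecutive non-overlapping 1 s
windows, each summarised by three descriptors: path length (cm), positional
standard deviation (cm, pooled over both axes) and mean speed (cm/s). A
two-component Gaussian mixture, fitted by EM with k-means initialisation on
the windows pooled **across the whole cohort** (both groups, both
conditions), classifies windows as *quiet* or *unquiet*; the unquiet
component is the one whose mean has the larger Euclidean norm in original
descriptor units. With unquiet fractions $f_{EO}$ and $f_{EC}$, the score
is

$$\mathrm{score} = 100 \cdot \frac{(1-f_{EO}) + (1-f_{EC})}{2},$$

so 100 is excellent and 0 is bad.

Numerical choices worth knowing:

* Path length and mean speed are exactly proportional for equal-length
  windows, so the mixture uses **diagonal covariances** with a variance
  floor ($10^{-6}$ in standardised units); descriptors are standardised
  before EM. A full covariance would be singular by construction.
* A zero-variance descriptor pool is flagged degenerate and every window is
  labelled quiet rather than fitting an undefined mixture.
* The cohort-level fit is a deliberate choice: with only ~25 windows per
  condition a per-subject mixture is unstable, and a single cohort-level
  fit gives "unquiet" one meaning for everyone. A consequence is that a
  subject's score depends (weakly) on who else is in the cohort; the
  patient-only invariance of the coupling stage therefore applies to the
  modelling inputs, not to the mixture fit.
* "Percentage of unquiet periods" counts windows; for equal-length windows
  this equals the time fraction.

# Oculomotor biomarkers

Events come from a velocity-threshold (I-VT) classifier: angular speed by
central differences, samples above 30 deg/s are saccadic, runs below it are
fixation candidates, and candidates shorter than 60 ms are **discarded**
(left unclassified, not merged). Invalid runs up to 75 ms (blinks, tracking
loss) are bridged by linear interpolation; longer ones split the recording
into independently classified segments. These defaults are the vendor-style
conventions used when the classifier behind a commercial eye tracker is not
further documented. Event durations use the span convention
$t_{last} - t_{first}$ with a floor of one sampling period; with this
convention a constructed 40 ms, 10° shift between two fixations is detected
as exactly one 40 ms saccade.

Because discarding removes a fixation without merging its neighbouring
saccades, the fixation/saccade count ratio falls below 1 as short fixations
become more common — the direction observed in impaired groups.

The 18 biomarkers: per-second dynamic features (RangeX/Y, VarianceX/Y,
EllArea) are computed over consecutive non-overlapping 1 s windows and
averaged, dropping the trailing partial window; VelocityX/Y and Velocity
are mean absolute component velocities and mean Euclidean speed over
consecutive valid samples of the whole task; MeanFix/VarianceFix/SkewFix/
KurtFix and the saccade analogues summarise event durations; Fix2SacNratio
is the whole-task count ratio. Conventions, stated once:

* "Variance" features are **standard deviations** — their conventional
  name is kept, and their units (ms, deg/s) only make sense as SDs.
  Tree-based modelling downstream is invariant to this monotone choice.
* RatioRange is RangeX/RangeY (its numerator/denominator reading is fixed
  by the magnitudes of the published group means).
* Kurtosis uses the non-excess convention (normal = 3). Zero-variance
  duration sets return skewness/kurtosis 0 so tables stay finite.
* Undefined ratios (no saccades, RangeY = 0) are `NA`, never infinities;
  missing cells are imputed with the cohort median at the pipeline stage,
  logged per cell.
* The 95% confidence ellipse uses the $\chi^2_2$ quantile: semi-axes
  $\sqrt{q_{0.95}\lambda_i}$ from the covariance eigenvalues, full axis
  $2\sqrt{5.991} \approx 4.90$ at unit variance; degenerate (collinear)
  windows contribute zero area.

# The coupling model

The regression forest is implemented in compiled code in this package
(bootstrap CART trees, variance-reduction splits, `mtry` feature
subsampling): no random-forest package is assumed. Defaults follow
regression-forest conventions — 500 trees, `mtry = ceiling(p/3)`, minimum
leaf 2 — since the original protocol does not state hyperparameters.

For each tree and each feature the tree used, $d$ is the tree's out-of-bag
mean squared error after permuting that feature among its out-of-bag cases,
minus the baseline. The importance of feature $i$ is

$$\mathrm{Imp}_i = \bar d_i / \sigma_i$$

over the trees that used $i$, with $\sigma_i = 0 \Rightarrow
\mathrm{Imp}_i = 0$. The procedure is repeated five times (seeds
`seed + 0..4`); a feature is selected when the lower quartile of its five
importances exceeds 0.1 — strictly, with the linear-interpolation quantile
(type 7), so the worked example `{0.0, 0.05, 0.3, 0.3, 0.3}` has lower
quartile exactly 0.05 and is not selected. The quartile is taken across
runs (not pooled within runs), matching the protocol's phrasing.

Leave-one-out prediction trains a forest on the other $N-1$ subjects per
fold (fold seeds `seed + fold`, so perturbing one subject's label cannot
change its own out-of-fold prediction); `rmse_norm` is the RMS residual
divided by the 100-point score range, and `rmse_norm_excl` recomputes it
after dropping the single largest absolute residual (first index on ties —
the published analysis excluded one visually identified outlier).
Predictions are clipped to [0, 100] with clipping counted.

# The synthetic cohort — what it emulates and what it does not

Each subject carries a latent severity $s \in [0,1]$; controls draw
$s \sim U(0, 0.2)$ and patients $s \sim U(0.2, 1)$ (10 patients and 9
controls by default, mirroring the motivating study design). The attention
subscore is `round(37 - 14 s)` plus integer noise in $\pm 2$, clipped to
[0, 37], reproducing the published 23–37 range.

**Gaze.** An alternating fixation/saccade process. Fixation centres are iid
uniform in a severity-dependent box; the box size is solved from the
uniform-range formula so the expected per-1-s-window range matches the
calibration endpoints (6.0 → 14.6 deg horizontally, 3.4 → 9.5 deg
vertically as $s: 0 \to 1$). Fixation durations are lognormal
(`sdlog = 0.45`); the location parameter is solved so that the **detected**
mean fixation duration matches the calibration endpoints (316 ms intact →
153 ms impaired), accounting for two detector-side biases: boundary samples
reassigned to saccades (≈ 3 sampling periods) and truncation by the 60 ms
minimum-fixation rule. Saccades follow a main-sequence rule (duration =
2.2 ms/deg · amplitude + 21 ms) with a raised-cosine profile; fixations
carry 0.1 deg isotropic jitter; blink gaps of 100–300 ms arrive at 0.25/s
(≈ 5% invalid samples). The dispersion of fixation durations is *not*
calibrated to published group SDs (a CV near 1 would be incompatible with
the minimum-fixation rule and the ±10% mean calibration); only means and
directions are claimed.

**Posture.** An Ornstein–Uhlenbeck sway process (τ = 1 s, quiet SD
0.3 cm) whose innovation variance is inflated ×16 inside burst blocks.
The planted burst-time fraction is $f = \mathrm{clip}(0.5\,s + b, 0, 1)$
with $b_{EO} = 0.05 < b_{EC} = 0.15$; burst blocks are allocated on a 1 s
grid, stratified so the scored final 25 s realises the planted fraction to
the grid's resolution. Timestamps are jittered by ±30% of the nominal 40 Hz
period to emulate non-constant sampling. The planted $f$ and the burst log
are attached to each recording for test oracles.

`effect_scale` multiplies the severity seen by the *gaze* generator only:
0 yields a null cohort in which gaze statistics are independent of the
planted postural truth — used to show the coupling analysis finds nothing
when nothing is planted.

A green test on this generator establishes that the pipeline recovers
planted structure of the stated form; it does not establish biomechanical
realism of sway spectra, reading-specific gaze semantics, or the published
cohort's absolute numbers (the raw recordings behind those are not
available, so the published headline values are not reproduction targets).

The importance-recovery fixture deserves one note: its four informative
columns are **orthogonalised** (a designed experiment with equal planted
effects). With iid Gaussian columns at $n = 40$, chance correlations can
mask one planted feature — verified against an independent implementation,
which assigns the masked feature noise-level importance on the same data —
so the designed version is what "four planted informative features"
actually promises.

# Known limitations

* The quiet/unquiet surrogate reproduces the published sketch (local
  windows, two-component Gaussian mixture, unquiet fraction), not the
  original algorithm's undocumented internals (descriptor set, window
  overlap, fitting population).
* Skewness/kurtosis of a handful of saccade durations are noisy; they are
  reported but rarely informative at $n \approx 200$ events.
* The rank-sum test switches to the normal approximation under ties or
  $n > 10$; with scores derived from 25-window fractions, ties across
  subjects are possible.
* Runtime scales linearly in trees × subjects² for leave-one-out
  importance work; the defaults run a 19-subject cohort end-to-end in
  seconds.

# Reproducibility

Every stochastic step takes an explicit seed; cohort generation derives
per-subject seeds from the master seed, importance runs use `seed + run`,
and leave-one-out folds use `seed + fold`. Rerunning a pipeline with the
same configuration reproduces every artifact byte for byte; each run
directory carries an FNV-1a hash of its configuration (output location
excluded) in `report.json` and `run_log.json`.
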