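---
title: "Quantifying ICG perfusion curves: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ICG perfusion curves: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icgquant)
```

## The problem

Indocyanine green (ICG) fluorescence angiography renders tissue perfusion as
a greyscale intensity signal on a near-infrared (NIR) camera. Sampling a
user-drawn box region of interest (ROI) over time — a "digital biopsy" —
yields a time–fluorescence curve whose shape reflects the underlying
tissue's perfusion kinetics: dye arrives, peaks, and washes out. Malignant
tissue retains ICG, so its post-peak washout is markedly slower than that of
healthy tissue, and scalar descriptors of the curve ("milestones") support
automated tissue classification.

Clinical curves come with acquisition problems that any quantitative
pipeline must handle: detector saturation when the dose is too high for the
tissue (the signal pins at the 8-bit ceiling and the curve shape is
destroyed), twin inflow peaks when the bolus is accidentally pushed in two
pulses, absolute-intensity differences driven by camera-to-tissue distance
rather than physiology, oscillatory noise from camera and tissue movement,
and videos that simply end before the slower milestones can be observed.
`icgquant` implements the full chain — simulation, extraction, QC,
conditioning, milestone features, imputation, and cross-validated
classification — with each mitigation testable against analytic ground
truth.

## The kinetic curve model

Clinical ICG videos are not redistributable, so the package ships a
generator whose curves have the same qualitative structure. The noiseless
model is piecewise: nothing before dye arrival at `onset_time_s`; a
gamma-variate-shaped bolus front

$$F(t) = P\left(\frac{\tau}{\tau_p}\right)^{\alpha}
         e^{\alpha\left(1 - \tau/\tau_p\right)}, \qquad \alpha = 2,$$

rising to the peak intensity $P$ over `time_to_peak_s` $= \tau_p$; then a
plateau-plus-exponential washout tail

$$F(t_{peak} + \Delta t) = P\,[\,p + (1 - p)\,e^{-k \Delta t}\,],$$

continuous at the peak. The plateau fraction $p \in [0, 1]$ models ICG
retention (the non-washing residual characteristic of malignancy) and $k$
the washout rate. The gamma-variate front is the standard shape for a
dispersed intravascular bolus; the plateau-exponential tail is the simplest
form that reproduces both fast healthy washout and malignant retention.

On the *normalized* curve the downslope at horizon $N$ seconds after the
peak has the closed form

$$\mathrm{ds}_N = \frac{(p + (1 - p)e^{-kN}) - 1}{N},$$

which is the oracle every milestone test compares against.

### Class presets

Presets anchor each tissue class to its characteristic normalized 10-s
outflow slope: healthy $-0.0065\,\mathrm{s}^{-1}$ (full washout, $p = 0$),
benign $-0.004\,\mathrm{s}^{-1}$ ($p = 0.3$), cancer $-0.001\,
\mathrm{s}^{-1}$ ($p = 0.6$). `washout_rate_for_downslope()` solves $k$
from the target slope and plateau. Per-ROI parameters are drawn with a 20%
coefficient of variation; inflow timing also differs mildly by class
(time-to-peak 15 / 20 / 25 s), reflecting the delayed perfusion of
neoplastic tissue.

### Artifacts and their order

Artifacts are applied in a fixed, documented order: kinetics → double bolus
→ movement noise and spike → overdose gain → truncation → clip to
$[0, 255]$.

* **Double bolus.** Modelled as two narrow bolus transients: a first pulse
  that washes through with a fast first-pass decay (0.25 s⁻¹, no
  retention) plus the delayed main pulse carrying the tissue's own washout
  tail. Both pulses rise over at most half the inter-bolus delay — a rise
  wider than that would fill in the trough and no human or algorithm could
  see two peaks either. Defaults give first/second peaks roughly 10 s
  apart.
* **Movement.** White Gaussian noise plus a low-frequency sinusoid
  (0.2–0.5 Hz, random phase), matching the oscillation that camera/tissue
  motion imprints on real traces. The default cohort uses 3 greyscale
  units of each (about $\sigma = 0.02$ in normalized units at the default
  150-unit peak). An optional Gaussian "camera lurch" spike is available
  but off by default: the emulated classifier cohort was acquired with a
  steadied camera, and a large spike on a flat malignant plateau becomes
  the global maximum, which is exactly the gross-movement failure mode the
  QC stage exists to expose rather than something the default cohort
  should contain.
* **Saturation.** Overdosing is an intensity gain (default 2.0) applied
  before clipping, pinning the curve at the ceiling — the
  persistent-plateau artifact of excessive dosing.

### Cohort shape and interrupted series

The default cohort emulates a rectal-neoplasia series: 37 patients (13
benign, 24 cancer) contributing 251 ROIs — healthy control ROIs from every
patient plus lesion ROIs of the patient's class (88 healthy / 46 benign /
117 cancer). Trace durations use a post-peak quota: offsets after the peak
are drawn from bands so that, out of 251 ROIs, exactly 11 end before the
200-s downslope horizon, 72 before 300 s and 106 before 400 s, with every
trace retaining at least 100 s after its peak. Offsets keep a 20-s guard
margin from the band edges so that the small jitter between the analytic
peak and the peak detected on the smoothed noisy curve cannot flip a
trace's missingness band. Sampling is 5 Hz (the tracker cadence is not
standardised in practice; the rate is exposed in the config and all windows
are specified in seconds so behaviour is rate-invariant).

## The processing pipeline

1. **Extraction** (`extract_traces`): each sample is the arithmetic mean of
   pixel greyscale values inside the static box (median available).
   No inter-frame motion tracking is attempted.
2. **QC** (`detect_saturation`, `detect_double_peak`): saturation is a run
   of ≥ 2 s at or above greyscale 254 ("at the top of the 8-bit scale" —
   a strict "\> 255" is unreachable on 8-bit data); double peaks are ≥ 2
   local maxima whose topographic prominence reaches 15% of the global
   maximum. Saturated traces should be excluded from kinetic analysis —
   their curve shape is destroyed, not merely noisy.
3. **Smoothing** (`smooth_trace`): Savitzky–Golay, default 11-s window
   (odd sample count at the trace's rate), polynomial order 3. The window
   is long enough to suppress the 0.2–0.5 Hz movement oscillation. For
   *twin-peak QC* a shorter 3-s window is used (`qc_report`'s
   `dp_window_s`): a smoothing window comparable to the ~10-s peak
   separation would merge the two peaks before detection.
4. **Normalization** (`normalize_trace`): every sample divided by the
   curve's peak reading. This removes distance-driven absolute-intensity
   differences; the pipeline smooths *before* normalizing so a noise spike
   cannot set the divisor.

Peak detection uses a linear-time hysteresis pass that is exactly
equivalent to thresholded topographic prominence (the exhaustive
`find_peaks` computation serves as its oracle in the tests). The *first*
prominent peak is reported, so a double-bolus curve yields the first-pulse
peak, matching the feature's name.

## Milestone features

From the smoothed, normalized curve: time to first peak (`ttfp_s`); time to
half-max on the rise (`t_half_s`, linearly interpolated); their ratio
(`time_ratio` — the ratio definition follows the perfusion-milestone
convention of the antecedent literature, since "time ratio" is otherwise
underdetermined); the least-squares upslope between the first 0.1-crossing
and the peak (robust to onset noise); downslopes at 10/50/100/200/300/400 s
after the peak, $(F(t_{peak}+N) - F(t_{peak}))/N$ with linear interpolation
at the horizon; and Fisher excess kurtosis of the full normalized series.
Horizons beyond the end of the recording are *missing*, never extrapolated
— extrapolation is the imputation module's job, and keeping the two
separate is what makes the leakage guarantees checkable.

## Imputation

Two deliberately separate mechanisms mirror how training and inference
differ:

* **Training tables** (`knn_impute_train`): each missing downslope is the
  mean of that column over the k = 5 nearest rows (Euclidean distance on
  z-scored features over the features observed in both rows). k and the
  metric are package choices — standard KNN-imputation defaults —
  exposed as arguments. Standardization uses moments of the observed
  values; imputed cells are not re-standardized.
* **Single test curves** (`exp_impute_test`): a test video has no
  neighbours, so its own observed tail is fitted with
  $F(\Delta t) = a e^{-b\Delta t} + c$ ($b \ge 0$) and missing downslopes
  are read off the fit. The offset $c$ accommodates retention; a pure
  2-parameter decay is available for very short tails where the offset is
  unidentifiable. The fit profiles $b$ over a log grid with $(a, c)$
  solved linearly at each point (separable least squares), then polishes
  with Levenberg–Marquardt at tight tolerance. The profile route matters:
  a slow exponential has a nearly collinear Jacobian and joint 3-parameter
  starts fail outright.

**Limitation — short tails.** Extrapolating a 200-s downslope from 10 s of
near-flat tail is fundamentally ill-posed: with retention-class kinetics
the tail decays under 1% in the observed window, so any noise comparable
to that (and the Savitzky–Golay bias in the half-window after the peak)
produces tens-of-percent errors in the extrapolated slope. The truncation
experiment below shows why this is tolerable: imputed values remain
class-*ordered* even when biased, so classification survives nearly
unchanged.

## Classification

`run_cv` runs stratified five-fold cross-validation (80:20 per fold, no
holdout) at ROI level by default, mirroring an all-available-ROIs design; a
`patient_level` grouping is offered because ROI-level splitting risks
within-patient leakage, and the choice is surfaced rather than silent.
Within each fold, *everything* learned — KNN imputations, feature
standardization, model selection, the classifier — is a function of
training rows only (`fit_fold` takes no test argument, which is the
structural no-leakage guarantee); test rows with missing cells are
completed by exponential fits to their own traces.

An exhaustive AutoML search is irreproducible and environment-dependent, so
the candidate set is fixed and small: a bagged K-nearest-neighbour ensemble
(25 bootstrap learners, k ∈ {3, 5, 7}), logistic regression, and a
200-tree random forest, selected by inner 3-fold cross-validated AUC on the
training rows. Two-way (cancer vs not-cancer) performance is standard
binary AUC-ROC with fixed direction; three-way (cancer vs benign vs
healthy) is macro-averaged one-vs-rest, a conventional choice where the
multiclass scheme is otherwise unspecified.

The incremental-downslope experiment adds horizons cumulatively (base
features always include `ttfp_s`, `time_ratio`, `ds10`; the run for horizon
$H$ adds all downslopes 50…$H$) under both missing-data policies. The
truncation simulation removes every downslope beyond 10 s post-peak for
*all* ROIs, refills them from 10-s tail fits, and re-runs the
classification for comparison with the full-data arm.

## Numerical choices and degenerate inputs

* Sample-grid alignment: closed-form milestone tests place the peak on the
  5 Hz grid; off-grid peaks incur at most one sample interval of timing
  error and the corresponding interpolation error in slopes.
* Ties at equal peak height resolve to the earliest sample (the feature is
  *first* peak); a trace still rising at its last sample raises a
  "peak not reached" error; boundary maxima are never peaks (this also
  immunises peak detection against the Savitzky–Golay edge overshoot at
  the start of a recording).
* All-zero traces cannot be normalized (error); traces shorter than the
  smoothing window raise an error suggesting a smaller window; flat tails
  short-circuit the exponential fit to $(a, b, c) = (0, 0, \bar F)$.
* Intensities are validated into $[0, 255]$ at construction; 8-bit TIFF
  round trips quantize to integer greyscale.

## What the tests do and do not show

The synthetic generator reproduces the *structure* the analysis relies on —
class-dependent washout, bolus-shaped inflow, saturation/double-bolus/
movement artifacts, interrupted series with a known missingness profile —
under a seeded, bit-reproducible RNG. Passing tests therefore demonstrate
that the pipeline measures what the model generates, that its invariants
(scale invariance, no leakage, determinism) hold, and that classification
is robust to the interruption patterns studied. They do not demonstrate
clinical performance: real curves carry tissue heterogeneity, dose and
camera variation, and inter-patient correlation that no simulator
reproduces, and published AUC values from clinical series are not
reproduction targets here. Problem sizes in the test suite (a 251-ROI
default cohort, 100-trace oracle sweeps, 200-tail fit sweeps, five seeds
for cohort-level claims) were chosen as the smallest sizes at which the
checked properties are stable.
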