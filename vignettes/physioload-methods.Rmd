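---
title: "Methods: from raw ECG/GSR to leave-one-subject-out expertise classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw ECG/GSR to leave-one-subject-out expertise classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physioload)
```

## The problem

Cognitive load varies inversely with task expertise, and it leaves traces in
two signals that wearable sensors record cheaply: the electrocardiogram
(ECG), through heart-rate variability (HRV), and the galvanic skin response
(GSR, also called electrodermal activity), through the tonic skin
conductance level and phasic skin conductance responses (SCRs). physioload
implements the full analysis chain that turns one baseline segment (about
2 min of quiet rest) and one task segment (about 10 min of active work) per
subject into a leave-one-subject-out (LOSO) evaluation of expert-vs-novice
classifiers, plus the supporting feature-selection and visualization steps.

Because no public corpus of paired ECG+GSR expertise recordings exists, the
package ships a synthetic cohort generator with complete ground truth
(R-peak times, SCR event times, per-subject generator parameters). All
validation is property-based against that ground truth: detector
sensitivity and precision, feature recovery of programmed physiology,
agreement of the spectral estimator with an independent oracle, planted
feature recovery for the selector, and end-to-end class discrimination.

## ECG preprocessing

`pt_filter_chain()` applies the classic QRS-enhancement cascade: a
zero-phase Butterworth bandpass of 5–15 Hz (order 3, run forward–backward so
R peaks do not shift in time), the 5-point derivative
$y(n) = \tfrac{f_s}{8}\,[2x(n) + x(n-1) - x(n-3) - 2x(n-4)]$, elementwise
absolute value, and a 150 ms moving-average integration. Rectification by
absolute value (rather than the squaring many implementations use) is a
deliberate choice; its narrower dynamic range is the reason the detector
keeps threshold estimates on two waveforms (below).

`detect_r_peaks()` scans the local maxima of the integrated waveform with
adaptive dual thresholds maintained as running estimates of signal- and
noise-peak levels, in parallel on the integrated *and* the bandpassed
waveform: on an accepted peak of height $h$,
$SPK \leftarrow 0.125\,h + 0.875\,SPK$; on a rejected candidate,
$NPK \leftarrow 0.125\,h + 0.875\,NPK$; the acceptance threshold is
$T_1 = NPK + 0.25\,(SPK - NPK)$, with $T_2 = T_1/2$ used by the search-back.
A candidate must clear $T_1$ on both waveforms. If no peak is accepted for
two seconds, the gap is re-scanned against $T_2$ (search-back accepts with
update weight 0.25). Three physiological guards complete the detector: a
200 ms refractory period, T-wave discrimination (a candidate within 360 ms
of the last beat whose steepest bandpassed slope is below half the beat's is
a T wave), and a final close-pair arbitration that keeps the larger
bandpassed apex of any two accepted peaks closer than 360 ms. Every
accepted peak is re-localized to the highest bandpassed sample within
±75 ms, so RR intervals are not biased by the integration-window lag.
Because every threshold is relative, detection is invariant to global
amplitude scaling. `compute_rr()` flags intervals outside 0.3–2.0 s;
flagged intervals are excluded from feature windows.

## GSR preprocessing

`filter_gsr()` low-passes at 1 Hz (Butterworth order 2, zero-phase) and then
applies a centered moving average of $2\,\mathrm{s} \cdot f_s$ samples
(exactly 1000 samples at the nominal 500 Hz) with reflect padding. The
moving average is deliberately expressed relative to the sampling rate so
the chain generalizes to other rates.

`detect_scr_events()` picks peaks on the heavily smoothed signal — which is
stable — but measures morphology on the 1 Hz low-passed signal, because the
2 s moving average attenuates a typical SCR peak by about 10% and smears its
onset by about a second. Onset is defined by slope: the last point before
the steepest rise at which the slope is below a quarter of the maximal
slope. The Bateman response rises at maximal slope from its very onset, so
on a zero-phase-filtered version this crossing sits near the kernel
midpoint, i.e. close to the true onset; it also cleanly separates phasic
rises from tonic drift, whose slope is orders of magnitude smaller. Events
with amplitude under 0.01 µS (numerical ripple) or rise time over 10 s
(tonic fluctuations) are discarded. Half recovery — the first time after
the peak at which the signal falls to onset plus half the amplitude — is
censored with a flag when the next event's onset or the end of the segment
intervenes; censored values are excluded from the HRT aggregates but the
events themselves are kept.

## Features and windowing

Task (and baseline) segments are windowed with `segment_windows()`: 10 s
windows with 5 s overlap for ECG, 30 s windows with 10 s overlap for GSR; a
600 s task segment yields 119 ECG and 29 GSR windows.

ECG windows carry 18 features: nine time-domain descriptors of the RR
intervals (min, max, range, mean, SD, coefficient of variation, SDSD, NN50,
pNN50 — NN50 counts successive differences above 50 ms, the standard HRV
reading), and nine frequency-domain ones (ULF, VLF, LF, HF and total band
powers, normalized LF and HF with denominator LF+HF, LF/HF, and the
sympathovagal ratio (LF+MF)/HF with MF = 0.08–0.15 Hz). Band powers come
from the Lomb–Scargle periodogram of the unevenly sampled tachogram —
implemented in-package, scaled as a one-sided PSD so that integrating it
recovers the sample variance — evaluated on a fixed grid (0.001–0.4 Hz,
step 0.001) and integrated by the trapezoidal rule. Two caveats are worth
stating plainly: ULF (< 0.003 Hz) and VLF are not physically resolvable
inside a 10 s window, so those two features are extrapolations of the
periodogram's low-frequency tail, retained for completeness; and on evenly
sampled series the estimator agrees with an FFT periodogram only at
frequencies above roughly one cycle per record length, which the acceptance
fixture respects.

GSR windows carry 25 features: mean/min/max/SD of the five per-event
descriptors (rise time, half-recovery time, amplitude, area, prominence
relative to the window's skin conductance level) across events peaking in
the window — the SD of a single event is reported as 0, the degenerate
within-window value — plus the SCL (window mean), mean absolute first and
second differences of the signal, band power in 0.01–1 Hz (Welch estimate:
10 s Hann segments, 50% overlap) and total periodogram power over 0–1 Hz.
Windows without any SCR have their event aggregates marked missing.

### Baseline-ratio normalization

Task features are divided elementwise by a per-subject baseline vector
(`baseline_normalize()`); baseline entries with magnitude below $10^{-9}$
yield missing-marked ratios, never infinities. The baseline vector is the
mean of the baseline windows' features, with one exception: the GSR
per-event aggregates are computed from the *pooled* baseline events rather
than averaged across windows. A 2 min baseline holds only a handful of
SCRs, so most 30 s baseline windows see a single event whose within-window
SD is the degenerate 0; averaging those zeros would make the SD-feature
denominators identically zero and silently delete every task window of the
subject. Pooling the baseline events gives the natural subject-level
dispersion instead.

Missing values are marked and the affected rows dropped at matrix assembly
(`assemble_matrix()`), never imputed; the dropped count is reported.
Subjects whose baseline physiology makes a denominator degenerate (e.g. a
single baseline SCR) can lose all their rows for the affected modality;
LOSO then simply runs on the remaining subjects, which is reported per
fold. Multimodal rows anchor on the 30 s GSR windows; each is paired with
the mean of the ECG feature vectors whose 10 s windows overlap it in time.

## Feature selection

`lasso_rank()` fits an L1-penalized linear regression of the 0/1 class
label on internally standardized features (population SD, which makes the
ranking exactly invariant to affine rescaling of any feature and to
duplicating every row) and reports standardized coefficients; a logistic
variant sits behind `family = "binomial"`. The penalty is either fixed (for
reproducibility) or chosen by 5-fold cross-validation with deterministic
cycling fold assignment; the one-standard-error rule is used deliberately —
a selector's job is to zero out noise, and the conservative CV rule does so
reliably (the planted-recovery test: 1 informative + 17 noise features at
n = 500 is recovered with all noise coefficients below 0.01 in over 90% of
seeds). `apply_threshold()` keeps features with |coefficient| > 0.01
(strict), ordered by magnitude with alphabetical tie-break; an empty
selection warns, and the pipeline falls back to all features with a logged
notice. The default pipeline ranks on all data before classification, and
the statistically sound alternative — selection inside each training fold —
is available by passing a per-fold selection to `run_experiment()`.

## Classification and evaluation

Four classifiers are supported (`classifier_spec()`): an SVM with
polynomial kernel of degree 2 (the inhomogeneous kernel, `coef0 = 1`; a
homogeneous one is an even function of the standardized features and cannot
separate sign-symmetric classes), cost 1; a fully grown Gini decision tree;
a random forest of 100 trees; and KNN with k = 5, uniform weights and
Euclidean distance. Features are standardized per fold using training-fold
statistics only, to avoid leakage. LOSO folds hold out all windows of one
subject; per-fold confusion counts use expert as the positive class, and
metrics follow the four standard formulas (accuracy, precision, recall, F1
as the harmonic mean), with division-by-zero returning 0 plus a flag.

Two aggregations are always reported: the mean of per-fold accuracy/F1
(`mean-over-folds`, the default) and the metrics of the pooled confusion
counts (`pooled-windows`). One consequence deserves emphasis: under LOSO
every test fold contains a single subject, hence a single true class, so
the per-fold F1 is degenerate (1 for a correctly classified expert fold, 0
for any novice fold by the zero-division rule) and the mean-over-folds F1
approximates the expert share rather than classification quality. The
pooled F1 is the interpretable one; both are in every report.

`tsne_embed()` projects a feature matrix to 2-D with t-SNE (perplexity 30,
10,000 iterations, learning rate 10 by default; the perplexity
auto-reduces with a warning when rows are scarce) and attaches the mean
silhouette width of the true labels as a scalar separability summary of
what is otherwise a visual check.

## The synthetic cohort generator

The generator emulates exactly the statistical structure the analysis
consumes, nothing more:

* **RR series** (`generate_rr_series()`): a mean-reverting AR(1) process
  (autocorrelation 0.2, 15% of the variance) plus two sinusoids at 0.095
  and 0.275 Hz (85% of the variance). The sinusoid split is solved so that
  the *total* LF/HF band-power ratio — sinusoids plus the analytically known
  AR(1) band floor — matches the `lf_hf_ratio` target. The modulators
  advance on the nominal beat clock; sampling them at realized beat times
  would frequency-modulate the series and bias the beat-averaged mean low.
* **ECG** (`synthesize_ecg()`): a sum-of-Gaussians PQRST template (1 mV R
  apex) at each beat, snapped to the sample grid so returned R-peak times
  are exact; additive 0.3 Hz baseline wander, 50/60 Hz powerline (default
  60), and white broadband noise.
* **SCR train** (`generate_scr_train()`): Poisson event times thinned to a
  minimum gap of 5 s (keeping events resolvable after the 1 Hz low-pass),
  log-normal amplitudes.
* **GSR** (`synthesize_gsr()`): a slowly drifting tonic level (0.005 Hz
  sinusoid) plus one Bateman response
  $A\,(e^{-t/\tau_d} - e^{-t/\tau_r})$ per event ($\tau_r = 0.75$ s,
  $\tau_d = 2$ s) plus white noise. By default the amplitude parameter is
  the peak rise (peak-normalized Bateman); `normalize = FALSE` exposes the
  raw multiplier, whose peak is $A \cdot b_{\max}$ with the closed form at
  $t^* = \frac{\tau_r \tau_d}{\tau_d - \tau_r}\ln\frac{\tau_d}{\tau_r}$.
* **Cohorts** (`generate_cohort()`): per-subject parameters jittered 3%
  around the class parameters; task segments apply the `task_shift`
  multiplier (heart period and HRV divided by it, SCR rate/amplitude and
  LF/HF multiplied — sympathetic activation under load); everything is
  deterministic given the seed and leaves the caller's RNG untouched.

The default class parameters encode a strongly separated cohort — experts
at mean RR 0.9 s, SDNN 0.06 s, LF/HF 1.5, 2 SCR/min, task shift 1.1;
novices at 0.7 s, 0.045 s, 3.0, 6 SCR/min, task shift 1.35 — values in the
range wearable studies report for rest versus active task load. The study
conditions are 5 subjects per class, 120 s baseline and 600 s task at
500 Hz, with modest sensor noise (0.05 mV broadband, 0.1 mV wander,
0.05 mV powerline on ECG; 0.02 µS white noise and 0.3 µS drift on GSR). No
distributional statistics of any real cohort are claimed: the defaults are
documented choices, and what passing tests show is that the pipeline
recovers *programmed* structure, not that real expertise is this easy. The
generator also omits motion artifacts, sensor dropout, ectopic beats and
non-stationary tonic trends, all present in real wearable data.

## Numerical choices and degenerate inputs

Zero-phase filtering uses reflected-edge padding to suppress start/end
transients. Moving averages are exact O(n) cumulative-sum rolling means
with reflect padding (unit DC gain: constants pass through unchanged). A
constant RR series yields exactly zero band powers; HF = 0 marks the ratio
features missing rather than dividing. Windows need at least 3 unflagged
intervals for time features and 4 for spectral ones; fewer marks the window
missing, never an error. Ties in threshold selection break alphabetically,
so selections are deterministic. All stochastic steps (generator, RF,
t-SNE, CV) accept seeds, and seeded calls restore the caller's RNG state.

Test and validation problem sizes are chosen to exercise the study
conditions at desk scale: detector oracles run 20 seeds of 60 s (ECG) and
300 s (GSR); feature recovery uses 2+2-subject cohorts with 60 s/180 s
segments; the end-to-end check runs one full 5+5 separated cohort and ten
full null cohorts at the complete 120 s/600 s durations.

## Known limitations

* The per-fold F1 degeneracy under LOSO described above.
* ULF/VLF from 10 s windows are extrapolations (kept for schema
  completeness; their normalized ratios still carry subject-relative
  information).
* Subjects with very sparse baseline SCRs can lose a modality entirely
  under the strict mark-and-drop policy; the pipeline logs the drop counts
  so this is auditable.
* The default selection-before-validation order reuses all subjects'
  data in the ranking; per-fold selection is the leakage-safe mode and is
  the right choice when the ranking itself is part of the claim.
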