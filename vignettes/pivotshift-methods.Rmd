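---
title: "Methods: segment-wise analysis of pivot-shift gyroscope signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment-wise analysis of pivot-shift gyroscope signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pivotshift)
```

## The measurement and its model

During a pivot-shift test a smartphone strapped to the tibial tuberosity
records angular velocity on three axes. The X axis follows the
flexion–extension arc of the maneuver; in an ACL-deficient knee the anterior
subluxation and its sudden reduction superimpose a short, sharp angular
velocity event late in the arc, and the amplitude of that event grows with
the degree of rotational laxity. The package's working model of a test is
therefore:

* an X-axis trace `ω_x(t)` dominated by a smooth flexion lobe,
* a reduction event concentrated in the final portion of the trace whose
  amplitude carries the injury grade (0–3),
* execution-dependent morphology: where the lobe and the event sit and how
  wide they are depends on how the examiner performed the maneuver (the
  eight "classes"), and
* additive, roughly white measurement noise of a few deg/s.

Analysis proceeds in fixed stages: quality control, min–max normalization of
the whole trace, division into three contiguous segments S1/S2/S3, feature
extraction on the original and normalized representations and on the Fourier
magnitude of normalized S3, then two classification stages (class, then
grade within class).

## Segmentation and normalization choices

No published rule fixes the segment boundaries, and inspection of example
traces suggests they were chosen visually around the maneuver phases. The
package defaults to *equal thirds*, with `|S1| = |S2| = floor(n/3)` and the
remainder going to S3 — S3 is the analysis target, so when a sample must be
assigned somewhere it goes there. An explicit-boundary strategy
(`segment_signal(..., "explicit", boundaries = c(b1, b2))`) supports
event-aligned analyses when the user knows where the phases are.

Normalization is min–max to [0, 1] computed over the **whole** test signal
before segmentation. Normalizing per segment would erase the inter-segment
amplitude ratios that several features depend on (e.g. the ordinate of the
S3 regression line is only meaningful relative to the trace's global
extremes). A consequence worth knowing: every feature of the normalized
representation is invariant to positive affine rescaling of the raw trace,
so gain differences between phone models do not move the class features.

## Quality control

Discarding non-analyzable tests (technical failures, misplaced device,
incorrect execution) is part of the procedure; the package makes the rules
explicit and configurable (`qc_config()`), with stable reason codes:

| rule | default | code |
|---|---|---|
| duration | 1–10 s and ≥ 50 samples | `DURATION_OUT_OF_RANGE` |
| non-finite samples | none allowed | `NAN_SAMPLES` |
| saturation | > 5% of samples at ±2000 deg/s on any axis | `SATURATION` |
| flat signal | zero variance on X | `FLATLINE` |
| amplitude floor | smoothed peak |ω_x| ≥ 5 deg/s | `AMPLITUDE_FLOOR` |

The amplitude floor is evaluated on a 0.1-s moving-average smoothed trace.
This is deliberate: the maximum of ~300 raw samples of N(0, 3 deg/s) noise
exceeds 5 deg/s almost surely, so a raw-sample peak rule would never fire on
a weak (misplaced-device) signal. Smoothing shrinks the noise peak by about
√(window length) while leaving a genuine 60 deg/s lobe essentially
untouched, making the rule a test of signal rather than of noise.

## Features

All features are deterministic functions of one segment:

* `segment_stats()`: max, min, mean, `range = max − min`,
  `rx = range + mean`, and the **population** standard deviation
  (denominator `n`; with ~100 samples per segment the difference from the
  sample version is negligible, and the population form is the natural
  descriptive statistic of a fixed segment).
* `linreg_features()`: ordinary least squares of value against elapsed time
  within the segment; the *ordinate* is the intercept at segment start.
* `fourier_magnitude()`: one-sided magnitude spectrum, bins
  `k = 0..floor(n/2)` at `k·fs/n` Hz, raw DFT sums (no 1/n scaling — only
  regression slopes over the spectrum are consumed downstream, and slopes
  do not care about a common factor).
* `shannon_entropy()`: Shannon entropy in bits of the normalized **energy**
  distribution `p_i = x_i²/Σx_j²`. The feature's role is to distinguish a
  trace whose energy is concentrated in one short event from one whose
  energy is spread out; an energy-based estimator does this without any
  binning choices, is deterministic, and handles the all-zero segment by the
  convention H = 0.
* `S3TF-P` is read as the slope of the regression line through the Fourier
  magnitude of *normalized* S3 over the non-DC bins, with frequency in Hz as
  the abscissa. The label admits a time-domain reading too ("slope of the
  linear regression of segment 3"), but the "TF" tag and the explicit
  listing of Fourier representations among the analyzed ones point to the
  spectral reading; since the time-domain S3 slope is recoverable from
  `S3n-O` and the segment mean, the spectral reading also adds more
  independent information. The choice is centralized in `spectrum_slope()`.

The class feature set (`S3n-STD`, `S3n-R`, `S3n-Rx`, `S3n-O`, `S3TF-P`)
lives on the normalized representation — the "n" suffix; the grade set
(`S1-Max`, `S3-Max`, `S2-R`, `S3-R`, `S3-STD`, `S3-We`, `S3TF-P`) on the
original deg/s scale, where amplitude *is* the signal of laxity. `S3-We` is
computed on original values; like the other grade features it is meant to
see amplitude structure, and entropy of the energy distribution is
scale-invariant anyway, so the representation choice only matters through
the baseline offset removed by normalization.

## Classifiers

Both stages use a single-hidden-layer feed-forward network with softmax
output (`nnet`, 12 hidden units, weight decay 1e-3, up to 500 BFGS
iterations), per-feature z-scoring with statistics from the training split
only, and a fixed seed for the validation split and weight initialisation.
With 5–7 inputs and at most 8 well-separated classes this is the smallest
standard architecture that does the job; deeper nets and adaptive-gradient
training add nothing here but more hyperparameters. Prediction always runs
through the package's own forward pass on the serialized weights (logistic
hidden layer, softmax output), so a model restored from JSON is guaranteed
to predict exactly like the in-memory one; the tests cross-check the forward
pass against `nnet`'s own `predict()`.

Two details are contracts, not accidents:

* **Determinism and permutation invariance.** Training rows are put into a
  canonical (lexicographic) order before the seeded split, so identical
  data give identical models regardless of row order.
* **Tie-break.** Equal posterior probabilities resolve to the lowest label
  index (`which.max`), so predictions are reproducible.

Grading is per class: one model per maneuver class 2–7, mirroring per-class
grade evaluation. Classes 1 and 8 — the executions furthest from the
standardized maneuver — are never graded (`gradable_mask()`).

## Statistical evaluation

* `paper_metrics()` reproduces the four per-class metrics of this
  literature from a (TP, FP, FN) triple. The per-class "accuracy" column is
  arithmetically `TP/(TP+FP+FN)` — the critical success index, not standard
  accuracy; the package exposes it as `accuracy_paper` to reproduce printed
  numbers without propagating a misleading name, and reports standard
  multiclass accuracy separately in evaluation reports.
* `chi_square_independence()` is the plain Pearson statistic with
  `E = row·col/N`, no continuity correction, upper-tail p. Printed p-value
  floors (e.g. "p = 0.00001") are treated as floors; the function returns
  the actual tail probability.
* `mann_whitney_u()` switches between exact enumeration (n_a + n_b ≤ 16,
  no ties; the full `choose(N, n_a)` distribution is enumerated) and the
  normal approximation with tie correction and a 0.5 continuity correction.
  The `method` field records the route. Calibration under the null
  (two-sided, 50+50, 1000 replicates) is checked in the test suite and
  recomputed by the acceptance script.
* `roc_auc()` sweeps thresholds over the unique scores and integrates by
  trapezoid, which equals the Mann–Whitney pair-counting estimator with
  ties counted ½ — an identity the tests verify against an O(n²) oracle.

## The synthetic-data generator

No raw clinical recordings are published, so the package ships a documented
stand-in. The X-axis waveform is

```
ω_x(t) = g·[ A_f·exp(−(t−t1)²/2σ1²) − grade·Δ·exp(−(t−t2)²/2σ2²) ] + ε(t)
```

with defaults A_f = 60 deg/s, Δ = 30 deg/s (so grades 0–3 give bump
amplitudes 0/30/60/90 deg/s), duration 3 s at 100 Hz, ε ~ N(0, 3 deg/s)
i.i.d., and Y/Z channels as leak-gain (0.3/0.2) copies of the deterministic
X waveform plus independent noise. `(t1, σ1, t2, σ2, g)` come from a fixed
per-class registry (`class_registry()`): classes 2–7 place the bump in the
final third at class-specific positions and widths, and stagger the flexion
lobe's center (0.8–1.5 s) and width (0.20–0.66 s) so that the lobe's tail
into S3 differs between classes by more than the noise floor. That last
point matters: at grade 0 the bump vanishes entirely, and the lobe tail is
then the only class signature visible to the S3-only class features. Class 1
truncates the recording to 30% of the duration (it always fails the QC
duration rule), and class 8 scales the whole waveform by 0.04 — a misplaced
device — which trips the smoothed amplitude floor at a high rate.

Default cohort composition: class probabilities follow the standardized-test
class distribution of the multicenter cohort (counts 11, 28, 81, 79, 90,
83, 21, 6 over classes 1–8, n = 399); grade probabilities are
(0.19, 0.486, 0.267, 0.057) — the reported 60/33/7% split of injured knees
scaled by an injured share of 0.81, the grade-0 share 0.19 being the
postoperative + follow-up fraction (83/437) of tests, since no grade-0
proportion is reported directly. Context is drawn conditional on grade
(grade 0 → postop/followup at 63:20, injured → office/preop at 136:180) and
side at the cohort's 204:233 L:R split. The registry and cohort constants
were fixed once at design time and are user-overridable but not tuned per
analysis.

What the generator does **not** emulate: joint kinematics (no biomechanical
model), accelerometer channels, evaluator-to-evaluator variability beyond
class morphology, autocorrelated sensor noise, drift, or variable sampling
rates. Passing the end-to-end recovery tests therefore shows that the
pipeline recovers labels *under this model's assumptions* — clean separable
morphologies with white noise — and says nothing about accuracy on clinical
recordings, where class overlap and artifacts are the hard part.

## Problem sizes and tolerances

The test suite and the acceptance script run end-to-end recovery on a
600-test cohort with a 20% holdout (the full suite finishes in well under a
minute),
Mann–Whitney calibration with 1000 replicates of 50+50, and oracle
equivalence on signals of n ≤ 64 (DFT, 1e-9), closed-form statistics
(1e-12), and random contingency tables (1e-10). Exact reproduction checks on
the published summary tables use the tables' printed precision. The
simulator's per-test cost is linear in `duration_s × sample_rate_hz`; the
defaults keep a 600-test run in the seconds range.

Degenerate inputs have defined behavior throughout: constant signals cannot
be normalized (`psm_degenerate_error`), all-zero segments have entropy 0,
zero metric denominators raise rather than return NaN, and a grade-model
class with fewer than 8 training rows or a single grade level is skipped
with a logged `TRAIN_SKIP` event rather than silently fitted.

## Known limitations

* The eight class labels are treated as given in training data; how they
  were originally assigned (clustering, thresholds, expert judgment) is not
  modeled, and the simulator's class morphologies are plausible but
  invented.
* The ROC ground truth and score are a package choice (injured = grade ≥ 1,
  scored by predicted injury probability); other operating definitions are
  configurable but not validated against any external data.
* QC cannot detect "incorrect device placement" from multi-axis signatures;
  the amplitude floor is a crude proxy.
* Min–max normalization is sensitive to single-sample outliers; QC's
  saturation and NaN rules catch the gross cases, but a robust
  (percentile-based) normalization is not implemented.
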