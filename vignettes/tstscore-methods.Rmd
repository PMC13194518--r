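---
title: "Scoring tail-suspension immobility from load-cell signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tail-suspension immobility from load-cell signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tstscore)
```

## The measurement problem

In the tail suspension test (TST) a mouse suspended by its tail alternates
between struggling (mobility) and passive hanging (immobility); the total
immobility time over a 6-min session indexes stress-coping behavior and is
the standard readout for antidepressant screening. A strain-gauge load cell
in the suspension bar converts struggle forces into a calibrated force
signal, sampled here at a nominal 80 Hz and held internally in grams.
`tstscore` turns such recordings into immobility bouts and summary
measures, calibrates the force threshold that separates the two states
against manual reference scores, quantifies agreement between scoring
methods, and aligns scored bouts with fiber-photometry calcium signals.

All times are seconds from recording start; bout intervals are half-open
`[start, end)` so that bouts tile a session exactly and durations add
without double counting. Internally, time accounting is done in integer
samples and converted to seconds once, which keeps the
immobile-plus-mobile total of a 360-s window exact.

## Two-step session start detection

A session begins when the resting platform is removed and the animal's
weight transfers to the bar. Detection proceeds in two steps.

**Step 1 — provisional start.** The raw trace is heavily smoothed with a
zero-phase 100-point moving average (forward-backward pass after
edge-replication padding; the double pass makes the effective impulse
response a symmetric 199-point triangle, so edges do not shift). The
*period threshold* `0.9 * mean + 0.1 * min` of the smoothed signal
separates the standing regime (a fraction of the body weight on the tail)
from the suspended plateau. The provisional start is the earliest time
after which the smoothed signal stays strictly above this threshold for at
least 270 s (a persistence long enough that no struggle lull or pre-start
excursion qualifies, while any genuine 6-min session does).

**Step 2 — refinement.** Within the post-start segment, the baseline is
the mean of the contiguous 800-sample window with the smallest standard
deviation in the middle third of the segment — a quiescent stretch of the
suspended-weight plateau. We read "the 800 lowest-variability points" as
one contiguous window rather than a pointwise selection: a contiguous
window has a physical interpretation (a single quiescent plateau epoch)
and a well-defined mean, whereas the union of scattered low-variance
points does not correspond to any epoch of the recording. The population
SD (divide by n) is used; at n = 800 the distinction is immaterial but it
must be pinned for the exhaustive-search oracle in the tests to match
bit-for-bit. Ties go to the earliest window.

The refined start is the first raw sample strictly exceeding the baseline
within ±30 s of the provisional start. The search is local on purpose: a
global first-exceedance scan would latch onto pre-start noise spikes, and
the refinement is by construction a small correction of the provisional
estimate. If no crossing exists in the interval the provisional start is
kept, with a warning.

A 360-s window starting at the refined start is then extracted, the
baseline subtracted, and the result band-pass filtered at 1–20 Hz. The
filter is a Butterworth of overall order 4 (realized as order 2 per band
edge), applied forward-backward with odd-reflection padding for zero
phase. The family and order are our choice — only the band is inherent to
the method — and both are exposed in the configuration
(`filter.band_hz`, `filter.order`). Struggling has its energy at roughly
2–10 Hz, comfortably inside the pass-band; baseline drift and the DC
plateau are removed.

Users can bypass detection entirely with a start override (e.g. taken
from the video), in which case the window is placed exactly at the given
time and only the baseline is still estimated for subtraction.

## Bout scoring

The band-passed signal oscillates through zero, so comparing it directly
with a g-valued threshold would fragment every struggle into
zero-crossing-spaced micro-bouts. The *movement envelope* — a rolling
maximum of the rectified signal over a centered 0.25-s span (20 samples
at 80 Hz) — tracks movement amplitude instead. A sample is mobile iff the
envelope strictly exceeds the detection threshold (default 0.792 g, the
calibrated global best threshold; see below). The envelope construction
and the absence of a minimum bout duration (`score.min_bout_s = 0`) are
declared conventions: the envelope is the minimal rectification consistent
with threshold-based bout segmentation, and no minimum bout duration is
imposed because none is part of the method. An optional merging rule
(shortest run first, earliest first) is available for users who want one.

Summaries per session: total immobility time; immobility latency (onset
of the first immobile sample run, 360 s if the animal is never immobile);
the cumulative immobility curve sampled at 1 s; and per-minute immobility
over the six minute bins. Total immobility is non-decreasing in the
threshold — raising the threshold can only reclassify mobile samples as
immobile — which is what produces the U-shaped error curve exploited by
the calibration.

## Threshold calibration

For each mouse the automated immobility time is computed at the five
candidate thresholds 0.4, 0.6, 0.8, 1.0, 1.2 g (chosen around the
sensor noise ceiling) and paired with the manually scored immobility time.
A Random-Forest regressor learns `(threshold, auto_time) -> manual_time`.
The data handling mirrors a careful ML protocol: an animal-level 75/25
train/test split (no mouse spans partitions), grouped 5-fold
cross-validation on the training mice, a randomized hyperparameter search
compared against the 200-tree baseline under the same grouped CV, and the
baseline kept unless tuning strictly improves the CV mean absolute error.
The baseline forest uses fully grown trees with all features considered
at each split, matching the defaults of the scikit-learn-style regressor
this protocol mirrors; the randomized search draws 25 specifications from
`ntree` 100–600, terminal-node caps {unlimited, 16, 32, 64, 128, 256},
`nodesize` 1–8 and `mtry` {1, 2}.

The *global best threshold* (GBT) is found by scanning a dense grid
(step 0.001 g) over the candidate range. At each grid threshold the
per-mouse automated time is obtained by monotone interpolation across the
candidates (or recomputed from the signal when traces are available), and
the objective

> mean over mice of | auto_time(θ) − model-predicted manual_time(θ) |

is minimized (smallest θ on ties). The objective was a genuinely open
design choice. We considered minimizing
`|predicted manual − observed manual|`, but that objective is nearly flat
in θ: the forest effectively identifies each mouse from its `auto_time`
feature and predicts its manual time at every threshold, so the
minimization degenerates to the tie-break. Using the model as a smooth
stand-in for the manual reference and asking where the automated score
matches it preserves the intended U-shape, recovers a known generating
threshold on synthetic cohorts, and reduces to the model-free objective
`|auto(θ) − manual|` (also exposed via `objective = "auto_vs_manual"`)
as the model approaches the reference. Per-mouse optimal thresholds are
computed model-free (argmin of `|auto(θ) − manual|`) and are reported for
validation only, with a check that the GBT lies within their range.

The default detection threshold 0.792 g is the published calibration of
this procedure on a 16-animal cohort; reproducing that number requires
the original recordings, so the package's tests instead verify that the
calibration recovers a known generating threshold (±0.05 g) on synthetic
cohorts with observer noise of SD 2 s.

## Agreement between scoring methods

Scoring methods operate at different native resolutions (80 Hz sensor,
30 fps video). Tracks are therefore resampled onto a common grid at the
smallest native step by nearest-neighbor assignment, which preserves the
binary structure; exact half-step ties resolve to the earlier sample for
determinism. Session spans may disagree by up to one native step by
default (video and sensor windows never end on the same instant); the
tolerance is widenable to the start-detection accuracy (0.5 s) when
comparing tracks anchored at independently detected starts. Tracks are
truncated to the overlapping span before gridding.

With immobile as the positive class, the package reports the confusion
counts, precision, recall, their harmonic mean F1, and Cohen's kappa
`(Po − Pe) / (1 − Pe)`, which corrects the observed agreement `Po` for
the chance agreement `Pe` implied by the marginal state frequencies —
important because immobility and mobility are naturally imbalanced.
Undefined precision or recall (an all-mobile track) maps to 0 with a
warning rather than an error, since pharmacologically activated animals
can genuinely produce such tracks.

## Photometry synchronization

Two-channel photometry (470 nm calcium-dependent, 415 nm isosbestic,
40 Hz) is motion-corrected by robustly regressing the signal on the
control: iteratively reweighted least squares with Tukey bisquare weights
(tuning constant 4.685, at most 50 iterations), so calcium transients are
downweighted as outliers while the shared multiplicative drift is
captured. Then `dF/F = (F − F_fit) / F_fit` and a z-score over the whole
session. Whole-session z-scoring (rather than a baseline epoch) is a
declared choice: the TST has no natural quiescent baseline epoch, and the
downstream comparisons are within-session. A perfectly explained signal
(dF/F identically zero) is given a zero z-score by convention; a constant
non-zero dF/F is an error, since its z-score is undefined.

Calcium transients are strict local maxima with topographic prominence of
at least 0.5 SD — the height above the higher of the two minima
separating the peak from larger neighbors (or the series edge). Peak
amplitude is reported as the z-score at the peak sample. The prominence
computation is implemented directly (and verified against a brute-force
oracle) so that its definition matches the classic `findpeaks`
convention exactly.

Bout-state summaries report, per bout, the area under the z-score curve
per second (trapezoidal), peak frequency, and mean peak amplitude, then
bout-wise means per state. Peri-onset alignment extracts ±1 s windows
around every bout onset on the photometry grid with an *event-purity*
mask: pre-onset samples must lie inside the immediately preceding bout
and post-onset samples inside the current bout; everything else —
including samples beyond the session edge — is masked and excluded from
every average. Peri-onset peak counts use the same event-pure intervals.
A sentinel test (poisoning all non-event-pure samples with 10^6 and
checking that no average moves) guards the mask against regressions.

## The synthetic-data generator

The generator exists so that every stage can be tested against known
ground truth without any recordings. A session is: a standing segment at
`standing_force_fraction` (default 0.2) of the body weight; a step to the
suspended weight at a known hang time; an alternating renewal bout
schedule (exponential durations, mean immobile bout 12 s, mean mobile
bout derived from the immobility-fraction target of 0.6); struggle bursts
present only during mobile bouts, modeled as 2–10 Hz band-limited noise
amplitude-modulated by rectified slow noise with scale 3 g (band-limited
noise rather than tones because struggles are broadband, and the band
must survive the 1–20 Hz analysis filter); and Gaussian sensor noise of
SD 0.13 g, matching a low-noise load-cell/amplifier chain with ±0.4 g
peak excursions. Body weights are drawn around 25.5 g. Bout durations are
floored at 0.5 s so every simulated bout is scoreable at video
resolution. Manual annotations are derived from the truth by jittering
interior boundaries (Gaussian SD 0.1 s, truncated below half the shorter
adjacent bout so bouts never reorder) and snapping to the 30-fps frame
grid. Cohorts assign per-subject seeds, spread hang times over 60–180 s,
and reduce the treated half's immobility-fraction target by the
treatment effect.

Synthetic photometry shares one multiplicative drift (slow bleaching
trend times a slow oscillation) across both channels, adds
exponential-kernel transients (~50 ms rise, ~500 ms decay) to the 470 nm
channel only — one at every mobility onset plus Poisson-timed extras
during mobile bouts — and Gaussian sensor noise (SD 0.05 a.u. against
baselines of 150–200 a.u.). The noise level describes a high-SNR rig in
which a 0.5-SD prominence floor cleanly separates transients from noise;
with noisier hardware the floor would need raising, which is why it is a
parameter.

What the generator does *not* emulate: tail-climbing artifacts, slow
sensor drift beyond the baseline step, occlusion-driven annotation
errors, inter-observer disagreement structure, hemodynamic or
photobleaching nonlinearities beyond the shared multiplicative trend, and
any biomechanically realistic struggle waveform. Passing tests on
synthetic data therefore demonstrate the correctness of the algorithms
under the stated signal model, not the field performance of the published
hardware.

## Numerical choices and degenerate inputs

* Sample-count arithmetic makes immobile + mobile = 360 s exact; the
  per-minute bins and cumulative curve are exact to float addition.
* Strict inequalities throughout (`> threshold`, `> baseline`) with
  closed-open persistence windows give deterministic boundary behavior.
* The baseline scan centers values before the cumulative-sum variance
  computation, so the fast path matches the exhaustive oracle to 1e-9
  even on long plateaus.
* Filtering pads by odd reflection (three seconds) before the
  forward-backward pass; the heavy smoother pads by edge replication
  (two window lengths). Both choices are part of the oracle contracts.
* Empty or too-short inputs fail with specific messages ("empty log",
  "corrupt timebase", "no post-start period found", "post-start segment
  too short for baseline", ...) rather than propagating NAs.
* All randomized components (simulation, splits, forests, the randomized
  search) are seeded; the full simulate-score-calibrate-evaluate pipeline
  is byte-reproducible under a fixed seed.

## Problem sizes in the test suite

The suite exercises full-scale single sessions (360 s at 80 Hz, 28,800
samples per window), a 16-subject cohort for calibration recovery, oracle
sweeps up to 50,000 samples, and 100-seed leakage scans; the complete
suite runs in well under a minute on one core. These sizes were chosen so
every property is tested at the scale the method actually runs at per
subject, while cohort-level analyses use enough subjects (8–16) to mirror
the published design.

## Known limitations

* The GBT objective and the envelope construction are declared
  conventions where the original description is silent; both are
  parameterized so alternative readings can be evaluated.
* Calibration quality degrades gracefully but noticeably when the
  automated-time curves are flat in the threshold (e.g. burst amplitudes
  far above the candidate range); the U-shape needs the thresholds to cut
  through the movement-amplitude distribution.
* The agreement module compares binary tracks only; graded mobility
  scores are out of scope.
* XLSX is supported for reading annotations; reports are written as CSV.
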