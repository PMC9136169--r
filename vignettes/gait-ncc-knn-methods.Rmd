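---
title: "Gait stability and symmetry features for fall-risk classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait stability and symmetry features for fall-risk classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitknn)
```

## The measurement model

A walking person produces quasi-periodic acceleration at each ankle. Two
properties of that signal carry information about fall risk in older
adults: **gait stability** — how closely consecutive strides of the same
leg repeat one another — and **gait symmetry** — how closely the left and
right legs mirror one another. `gaitknn` quantifies both with sliding
normalized cross-correlation (NCC) and classifies the resulting feature
vectors with k-nearest neighbors.

The pipeline operates on bilateral tri-axial ankle acceleration sampled at
120 Hz, with the axis convention x = anterior–posterior, y =
medio-lateral, z = vertical (in g). Four per-sample signal sources are
supported: the three axis components and the root-sum-of-squares magnitude
`RSS = sqrt(ax² + ay² + az²)`. The RSS is directionless: it is exactly
invariant under any rotation of the sensor, which matters because a
strap-mounted sensor never sits on the ankle the same way twice.

### Preprocessing

1. *Filtering.* Each axis is low-pass filtered with an 8th-order
   Butterworth design, cutoff 20 Hz, run forward and backward. Zero-phase
   application matters: a causal filter would delay the heel-strike
   valleys and misalign segmentation. Because the filter is applied twice,
   the effective magnitude response is the squared single-pass response;
   at the cutoff the gain is exactly 1/2, and a 40 Hz probe is attenuated
   below 1e-4. The series is padded by odd reflection (10·(order+1)
   samples) before filtering so edge transients do not leak into the
   signal; this also preserves constants exactly.
2. *Heel-strike detection.* Heel strikes appear as sharp valleys of the
   filtered x-axis. Candidates are local minima below `mean − 0.5·SD` of
   the series; candidates closer than 0.5 s resolve in favor of the
   deeper valley; minima within a quarter second of either end of the
   recording are ignored (a strike cannot be confirmed against the
   boundary). Both thresholds are exposed as arguments.
3. *Segmentation and normalization.* Cycles are half-open intervals
   `[strike_i, strike_{i+1})`, so they tile the inter-strike span exactly.
   The five midsection strides (start offset `floor((n−5)/2)`) are kept —
   walkway acceleration and deceleration live at the ends of a 10 m pass —
   and each cycle is linearly resampled to L = 100 points, removing
   stride-duration differences. Trials that cannot supply seven segmented
   cycles per side are rejected with a diagnostic rather than padded;
   downstream cohort functions quarantine such trials instead of failing
   the whole run.

### The NCC statistic and the gait-pattern vector

For a template `α` of length N and a record `β` of length M ≥ N, the NCC
series evaluates, at each shift t = 0..M−N, the Pearson correlation
between `α` and the window `β[t+1..t+N]`, each centered on its own mean.
Every coefficient lies in [−1, 1] regardless of signal amplitude, which
immunizes the features against gain differences between sensors and
participants.

Per trial and source, the record for each side is the concatenation of its
five normalized cycles (M = 500) and the template is one complete cycle
(N = 100), taken by default from the middle (third) midsection cycle of
the side named by the comparison's first letter — the middle cycle avoids
boundary strides, and the choice is exposed as `template_index`. Four
series result: LL, RR (stability) and LR, RL (symmetry), each with
M − N + 1 = 401 coefficients. Each series is reduced to its arithmetic
mean `M(·)` and its variability `V(·) = (max − min)/mean`; the eight
numbers, ordered `(M(RR), V(RR), M(LL), V(LL), M(RL), V(RL), M(LR),
V(LR))`, plus the class label (0 = recurrent faller, 1 = non-faller) form
the gait-pattern vector.

Two numerical properties of this statistic are worth knowing. First, for a
perfectly periodic record the sum of the circular autocorrelation over one
period is exactly zero, so the mean of an NCC series is pinned near
1/(M−N+1) ≈ 0.0025 — only the aligned-peak excess lifts it — and falls
toward zero as strides decorrelate. Second, `V` divides by that small
mean, so it is a strong amplifier of degradation but is undefined when the
mean vanishes; means below 1e-9 in absolute value raise a "degenerate
variability denominator" error rather than returning an arbitrary number.
A constant record window likewise has no defined correlation; its
coefficient is recorded as 0 with a warning (one flat window should not
abort a cohort run), whereas a constant template is an error.

### Classification

kNN with Euclidean distance over the eight features, majority vote.
Determinism is part of the contract: neighbors are ranked by (distance,
training index), so equidistant neighbors resolve to the earliest training
row, and a tied vote (possible only for even K) resolves to the class of
the single nearest neighbor. Features enter the distance unscaled by
default — the mean features are bounded and the variability features share
a scale — with optional per-fold z-scoring behind `scale_features`.

Model selection and evaluation use seeded, stratified 5-fold
cross-validation: within each class, vectors are shuffled and dealt
round-robin, so per-class fold sizes differ by at most one. K is chosen
from the odd grid 3, 5, 7, 9, 11 by minimal cross-validated error, ties
toward the smaller K; K = 1 is excluded because the single nearest
neighbor overfits. Because the default design pools both trials of each
participant, the two trials of one participant can fall into different
folds; `group_by_participant = TRUE` keeps them together, which is the
stricter (recommended) protocol for real cohorts, at the cost of
comparability with the pooled design. The report carries the full panel —
sensitivity, specificity, precision, recall, F1 per class, overall
accuracy, and MCC — with the non-faller class as the positive class in the
primary layout. Any metric with a zero denominator is reported as `NaN`
and named in a warning, never silently coerced to 0.

## The synthetic cohort

No public recordings exist for this design, so the package ships a
generator whose defaults *are* the study conditions: 15 non-fallers and 12
recurrent fallers, two 10 m walks each, 120 Hz, yielding 54 labeled
gait-pattern vectors per source. Group-level parameters anchored in the
study population: stance fraction 57.4 % (SD 2.2) for non-fallers vs
58.3 % (SD 4.9) for fallers; 10 m walk duration 8.43 s vs 8.80 s, with
per-trial spreads derived from the reported interquartile ranges; stride
duration 1.05 s vs 1.10 s (a plausible cadence for those walk times).
Participant-level profiles are drawn around the group profile — two trials
of one participant must resemble each other more than two participants do
— and every trial guarantees at least nine strides so the five midsection
strides always exist (10 m at these cadences yields 8–9 strides; the floor
only binds in edge cases).

### Waveform model

Each cycle of each axis is a sum of wrapped Gaussian bursts over cycle
phase: a deep negative anterior–posterior burst exactly at heel strike
(−2 g), a vertical loading spike just after it, and stance/swing bursts
placed relative to the stance fraction, on a 1 g gravity baseline for the
vertical axis. The right leg runs half a cycle out of phase. Heel-strike
times are snapped to the sample grid, so the simulator's ground-truth
valley indices are exact integers; in noiseless mode the detector recovers
them exactly, and with stride-timing jitter to within ±2 samples.

### How gait quality degrades

Designing the degradation needed care, because the NCC statistic is
deliberately insensitive to many nuisance transformations: a pure
per-cycle amplitude rescaling is removed by the Pearson normalization, a
global left-right time offset is removed by segmentation re-alignment, and
stride-duration differences are removed by time normalization. Mechanisms
that survive are *shape* changes:

- **Stability degradation** (`amplitude_jitter`): per-cycle burst-amplitude
  jitter; a variance-preserving rotation of the stance/swing waveform
  toward a fixed orthogonal equal-variance shape, which sets the
  correlation between two cycles to the cosine of their angle difference
  while leaving each cycle's variance — and hence the NCC normalization —
  untouched; impact-burst width jitter; and cycle-to-cycle timing scatter
  of the vertical loading spike (the heel-strike-to-foot-flat interval is
  poorly reproduced by an unstable gait).
- **Symmetry degradation** (`asymmetry_amp`, `asymmetry_phase`): a
  persistent alternating-sign reshaping, shape rotation, widened impact
  transient, and delayed vertical loading spike on the right leg. The
  loading-spike delay grows with both asymmetry parameters: a weaker,
  amplitude-asymmetric push-off also delays the contralateral loading
  response, and timing shifts of a sharp transient are what the NCC
  responds to most strongly.
- **Sensor imperfection** (`noise_sd`, `mounting_sd`): white sensor noise,
  and a per-trial strap-mounting rotation (heading plus a smaller tilt)
  that mixes the axis channels while preserving the per-sample vector norm
  exactly. The mounting rotation is why the RSS source classifies better
  than the x source here: axis features move with the strap, the magnitude
  does not.

The x-axis participates in the shape-degradation mechanisms at reduced
weight (anterior–posterior motion is mechanically constrained by the
walking direction, and the heel-strike valley must stay anchored for
detection), which concentrates the class signal in the medio-lateral,
vertical, and RSS channels.

Faller profiles differ from non-faller profiles in all four degradation
parameters. The magnitudes are generator choices, fixed once, selected so
that the two classes are separable but overlapping — the design targets
roughly 90–95 % cross-validated accuracy with the RSS source, a realistic
regime for this kind of biomarker rather than a trivially separable one.

### What the generator does and does not emulate

It emulates: quasi-periodicity with a dominant heel-strike valley,
stance-fraction and walk-duration differences between groups,
participant-level correlation between repeated trials, stride-to-stride
shape variability, persistent bilateral asymmetry, sensor noise, and
mounting variation. It does not emulate: musculoskeletal dynamics,
stance/swing sub-phase structure beyond the stance fraction, sensor drift
within a trial, gyroscope information, turning or stopping, or pathology
beyond the stability/symmetry axes. Passing tests on this cohort therefore
demonstrate that the pipeline recovers the statistical structure the
method assumes — not that the classifier's accuracy generalizes to any
real population.

## Parameter-sweep design

The monotone-degradation checks (increasing `amplitude_jitter` must lower
the mean M(LL)/M(RR); increasing `asymmetry_amp` must lower mean
M(LR)/M(RL)) are run ceteris paribus on a clean base profile: small fixed
jitters, no stride-duration jitter, no mounting rotation, sweeping one
parameter over four levels with 60 paired seeds per level. Holding
stride-duration jitter and mounting at zero isolates the swept parameter:
both introduce segmentation- and orientation-level variation whose effect
on the tiny NCC-series mean (order 1e-3) is not attributable to the swept
mechanism. Paired seeds reuse the same underlying draws at each level, so
the comparison is a scaling of the same perturbation rather than a fresh
sample.

## Numerical choices and degenerate inputs

- Filter: `signal::butter` + `signal::filtfilt` with odd-reflection
  padding; cutoff ≥ Nyquist and too-short series are validation errors.
- Interpolation: linear (`stats::approx`); exact on affine inputs, error
  bounded by h²/8·max|f''| on smooth ones; the first sample is preserved
  exactly; L < 2 is an error.
- NCC: vectorized via an embedded window matrix; coefficients clamped to
  [−1, 1] against floating-point overshoot; agreement with a naive
  double-loop evaluation to 1e-10 is asserted in the tests.
- Detection: fewer than two plausible valleys raises "insufficient gait
  cycles"; a monotone ramp or constant series therefore errors rather
  than returning nonsense.
- kNN ties and vote ties are resolved deterministically (see above), so
  a run is bitwise reproducible from its configuration and seed.
- Cohort runs quarantine failing trials with a reason instead of
  aborting; the quarantine list is attached to the feature table and a
  warning is raised.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
the study's own scale: cohorts of 54 trials (~1100 samples per leg per
trial), NCC oracle checks on 1000 random template/record pairs, classifier
oracle checks on up to 50 vectors, parameter sweeps of 4 levels × 60
trials, and accuracy estimation over 10 cohort seeds. The complete suite
runs in about a minute on one CPU.

## Known limitations

- The NCC-series mean is structurally pinned near 1/(M−N+1) for stable
  gait, so the variability feature V divides by a near-zero quantity; V is
  the dominant coordinate in the unscaled Euclidean distance and is heavy
  tailed for strongly degraded gait. This mirrors the published feature
  definitions; `scale_features = TRUE` is available where a better
  conditioned distance is wanted.
- With two trials per participant pooled before cross-validation, a
  participant can appear in both training and test folds; the grouped
  mode avoids this but changes the protocol.
- The cohort generator's class contrast is a stylized model of gait
  degradation; its parameters are calibrated to a target operating regime,
  not fitted to measured distributions.
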