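---
title: "Methods: real-world activity recognition from a wrist accelerometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-world activity recognition from a wrist accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Activity classifiers for wearables are usually trained on data collected in
supervised protocols: a fixed device orientation, scripted one-minute bouts,
an observer checking execution. Free-living ("in-the-wild") data are
different in almost every inconvenient way — participants wear the band
however it sits, interrupt activities mid-bout, and label their own data
after the fact, producing boundary errors and outright overlapping labels.
`wristhar` implements a complete pipeline for this setting: label cleaning,
windowing, leakage-safe per-participant splits, a compact 1D convolutional
classifier with rotational augmentation, transfer-learning personalization,
and a controlled-vs-real-world cross-context comparison — all exercised on a
synthetic cohort generator that reproduces the structure of such data.

## Label cleaning

Self-reported intervals are half-open `[start, end)`; touching intervals do
not overlap. Overlaps are resolved by a left-to-right sweep in start order,
re-checking each edited pair:

* partial overlap: the contested range is excised from **both** intervals
  (the earlier one's end moves back to the later one's original start, the
  later one's start moves forward to the earlier one's original end);
* full nesting: the enclosing interval is truncated at the nested interval's
  start and the nested interval is deleted;
* identical spans (and the shared-start corner case, where truncating the
  encloser at the shared start empties it): both intervals are deleted.

The longer/shorter rule is undefined for identical spans, so deleting both
is this implementation's tie-break; similarly, adjacent same-activity
intervals are *not* merged after correction. Every edit is logged, and the
total labeled duration always equals the pre-cleaning duration minus the
logged discard — a conservation law the test suite asserts, together with
idempotence and agreement with an independent per-second brute-force oracle.

## Signal processing and windowing

Raw device units are mapped affinely onto \[-2, 2\] (representing ±2 g) and
clipped. Higher-rate signals (the controlled protocol records at 50 Hz) are
downsampled to the working rate of 32 Hz by averaging contiguous
`1/32` s bins; empty bins propagate as gaps rather than being interpolated.

Windows are 12 s with 50% stride — a 3×384 matrix at 32 Hz. The window grid
restarts at each label interval's start (aligned to the sensor's own sample
grid), and a window is kept only when it lies entirely inside one cleaned
interval with all 384 samples present (each expected timestamp matched
within a quarter sample period). No imputation is performed. Under these
rules a gapless interval of `T` seconds yields `floor((T-12)/6)+1` windows,
which reproduces the reference per-budget counts (120 min → 1199, 10 min → 99,
5 min → 49); that correspondence is why full containment was chosen over
the alternatives (global grids, partial-overlap windows) that do not.

## Partitioning

Each participant's data per activity is split into a *personalization set*
(the earliest windows filling a fixed budget: computer table 120 min,
cycling/running/walking 10 min, standing still 5 min), a discarded 2-minute
leakage gap, and the *hold-out set* (everything after). An activity is
excluded for a participant whose total labeled time is below
`budget + gap + 0.5·budget`; the gap counts toward neither side (the
accounting question is ambiguous; excluding it is the stricter reading).

The pooled collection span is cut into 8 equal-duration absolute-time
chunks, identical cut points for all participants, so late joiners have
empty early chunks. Cumulative dataset `k` (CDS k) is the union of chunks
1..k. General models are leave-one-participant-out per CDS; participants
absent from a CDS share a single full-CDS model, trained once. The
personalization fractions 20–100% take time-ordered prefixes
(`floor(fraction · n)` windows per activity), so the fraction sets nest.

## The classifier

Seven stride-1 1D convolutional layers (kernels 16, 17×6; swish), global
average pooling, dense 32 and 16 (ReLU), softmax. The kernel sizes give a
receptive field of exactly `1 + 15 + 6·16 = 112` samples — 3.5 s at 32 Hz.
Only the layer counts, dense widths and the 3.5 s field are fixed
constraints; kernel sizes, channel widths (default 32, 32, 64, 64, 64, 128,
128) and global average pooling are this package's defaults, chosen as the
least surprising stack meeting the constraints, and are configurable.

Regularization follows the training regimes: spatial (whole-channel)
dropout after every conv activation, plain dropout between dense layers,
Gaussian noise added to the input and — transiently, per forward pass — to
the weights of the first two conv layers. The *rotational augmentation
layer* left-multiplies each training window by a random proper rotation:
draw a 3×3 standard-normal matrix `M`, blend `B = (1-s)I + sM`, Gram-Schmidt
orthonormalize `B`'s columns, and flip the last column if the determinant is
-1. `s = 0` gives the identity exactly; `s` is 0.2 in the real-world regime
and 0.1 in the controlled regime. This mimics the wristband sitting slightly
differently on the wrist.

Two regimes are preconfigured: `idlab` (105 epochs, Adam, lr 8e-4 decayed
×0.3 every 30 epochs, dropout 0.15, noise 0.03, batch 600) and `controlled`
(270 epochs, lr 5e-3 decayed ×0.3 every 50, dropout 0.075, noise 0.015,
batch 600). The loss is categorical cross-entropy. Training is
deterministic given the seed.

The network engine is a purpose-built compact implementation: forward and
backward passes are formulated as im2col-free shifted matrix products
executed by BLAS, with the convolution inner loops in compiled code
(`src/conv1d.cpp`). Analytic gradients are verified against finite
differences in the test suite.

## Personalization

Transfer learning freezes conv 1–3 and both dense layers and continues
training conv 4–7 on the target participant's personalization windows. The
softmax layer is also frozen by default — only the conv layers are named as
trainable in the protocol this follows, and the flag `freeze_softmax =
FALSE` exposes the other reading. The optimizer switches to SGD with the
learning rate raised (×10 by default), and regularization strengthened
(noise and dropout ×2, 60 epochs) — the direction of these changes is part
of the protocol, the magnitudes are this package's defaults and are all
configurable. Frozen parameters are returned bit-identical, which the tests
verify by exact comparison.

## Metrics

Per-class precision and recall from the confusion matrix; F1-micro from
globally pooled counts (equal to plain accuracy for single-label data, an
identity the tests assert); F1-macro and support-weighted F1; balanced
accuracy as mean per-class recall; logloss with probabilities floored at
1e-15. Hold-out sets legitimately lack some activities for some
participants, so zero-support classes are excluded from the balanced
accuracy and F1-macro averages by default (and reported); a strict flag
includes them as zeros instead.

## The synthetic cohort generator

The generator emulates the *structure* of in-the-wild collection, not exact
real signal statistics: per-subject cadences,
amplitudes, posture-gravity directions and a wrist-orientation rotation
applied to the whole stream; locomotion as three harmonics with relative
amplitudes 1/0.4/0.15 over activity-specific axis mixes plus white noise;
static activities as gravity plus a small incidental oscillation.
Real-world mode adds activity interruptions (5–30 s, absorbed into the
surrounding self-report label with the subject's labeling bias), boundary
jitter, overlapping labels created by extending an interval past its
successor's start, occasional mislabels, and sensor gaps. Controlled mode
is the lab protocol: 50 Hz, exact-duration uninterrupted bouts, zero label
noise, identity wrist orientation, and cadence/amplitude draws narrowed to
the central fifth of the real-world ranges — supervised "proper" execution
compresses inter-subject variability, and that compression (not just
orientation) is what creates a realistic domain gap when a
controlled-trained model meets free-living data.

Passing tests on this generator demonstrate that the pipeline's mechanics —
cleaning, windowing, splitting, training, personalization, evaluation —
behave as specified under realistic structure. They do not establish
accuracy numbers on real recordings: the generator's parameter ranges are
plausible but uncalibrated against any real cohort, real signals are far
less stationary, and real label noise is not independent across intervals.

## Numerical and scale choices

Timestamps inside bouts are exact multiples of the sample period, which
makes window-count formulas exact; "gapless" tolerates timing jitter up to
a quarter sample period. Equal-span overlap ties remove both intervals.
Chunk boundaries default to equal-duration bins over the pooled span but
are configurable. Probability rows must sum to 1 within 1e-6; rotation
matrices must be orthonormal within 1e-6.

The shipped demonstration and test configurations scale the full design
down so a full grid runs in minutes on one CPU: six-subject cohorts with
minutes rather than weeks of data per activity, budgets of 12/3 min with a
30 s gap (`demo_budget()`), two chunks, a narrow-channel stack
(4,4,6,6,6,8,8 — same 3.5 s receptive field), and short schedules with a
correspondingly higher learning rate (3e-3; a handful of epochs provides
few optimizer steps, so the full-scale rate of 8e-4 would leave the model
underfit). These sizes are the package's own demonstration choices; the
full-scale regimes remain the defaults for real data.

## Known limitations

* The generator's realism is structural; none of its parameters are fitted
  to real recordings.
* The CNN engine is single-threaded BLAS; it is sized for desk-scale
  cohorts, not weeks of data at full channel widths.
* The GBT baseline tunes over a small explicit grid rather than a full
  search, and the 42-feature inventory is this package's declared canonical
  layout (the historical inventory it stands in for was never published in
  full).
* Cross-context experiments share one four-activity vocabulary; the
  computer-table class has no controlled-protocol counterpart and is
  excluded there.
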