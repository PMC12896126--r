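---
title: "Detecting R-waves in surface EMG: model, simulator and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting R-waves in surface EMG: model, simulator and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3)
library(rwavenet)
```

## The problem

Surface EMG electrodes placed over the chest record a superposition of two
bioelectric sources: the skeletal-muscle signal they are meant to capture
and the heart's electrical activity. The sharp R-wave of each QRS complex
survives in this mixture, which means a chest-worn EMG garment can, in
principle, double as a heart-rhythm monitor — no dedicated ECG channel
required. What stands in the way is the muscle signal itself: during
exercise its amplitude can rival or swamp the cardiac component.

`rwavenet` treats R-wave extraction as a supervised sequence-segmentation
problem. A one-dimensional convolutional autoencoder maps a fixed-length
window of the raw mixture to a per-sample probability that each sample
belongs to an R-wave. Runs of supra-threshold samples are interpreted as
beat events, scored with an event-based precision/recall/F protocol, and
chained into a rhythmogram — the R-R interval series on which
heart-rate-variability analysis and tachycardia/bradycardia screening are
built.

## Preprocessing and labeling

Recordings are single-channel traces at 500 Hz. Each recording is min-max
normalized to $[-1, 1]$ *as a whole* and then fragmented into
non-overlapping windows of 1600 samples (3.2 s); a trailing remainder is
dropped. Normalizing per recording rather than per window was a deliberate
choice: per-window scaling would let a noise-only window inflate its
contents to full scale and would distort the relative amplitude of R-waves
across a recording. (Whether to scale per recording or per fragment is
genuinely open; this package fixes the per-recording convention and
documents it.)

The label for a window is a binary mask of the same length: each annotated
R-apex contributes five consecutive ones centered on the apex, zeros
elsewhere. At 500 Hz five samples span 10 ms, comfortably inside any
physiological QRS. Two consequences of this convention are enforced rather
than left implicit:

* apexes closer than 6 samples would merge their runs, which at 500 Hz
  would mean a heart rate above 5 000 bpm, so such annotations are
  rejected as corrupt;
* a run clipped by a window boundary keeps its clipped portion in each
  window, and the window containing the apex *owns* the event for
  evaluation. This preserves the total event count; the clipped ghost in
  the neighbouring window is deliberately not a label event there.

All sample indices in the package are 0-based, matching the on-disk
annotation format; this is stated on every relevant help page because the
off-by-one is the classic failure mode of this arithmetic.

## The detector

The network is an encoder–decoder stack of one-dimensional convolutions.
The default encoder is `(kernel 9, 16 filters, stride 2)`,
`(9, 32, 2)`, `(5, 64, 2)`: wide kernels early to see broad signal
context, a smaller kernel at depth for precise localization, and stride-2
downsampling in place of pooling, so a 1600-sample window compresses to a
bottleneck of length 200. Batch normalization follows each encoder
convolution; a single dropout layer (rate 0.3) sits at the bottleneck. The
decoder mirrors the encoder with transposed convolutions back to full
length, and a final single-channel convolution with a logistic output
yields the per-sample probability trace.

Supervision uses per-sample binary cross-entropy against the mask. R-wave
samples are ~1–2% of each window, so the positive class is up-weighted
(`pos_weight`, default 10). The optimizer is Adam (learning rate `1e-3`,
batch 32), with early stopping on a held-out validation loss (patience 20
within a 200-epoch budget by default). Loss choice, optimizer, filter
counts, depth, dropout rate and placement are all configuration — none of
them is forced by the architecture — and the defaults above are
conventional values for a small fully-convolutional segmenter. The whole
network, including the convolution and transposed-convolution kernels and
their gradients, is implemented in this package (RcppArmadillo for the
heavy primitives); its correctness oracle is a finite-difference gradient
check in the test suite, exact to ~1e-6 relative error.

Determinism: initialization, batch shuffling and dropout all draw from a
seed recorded in the configuration, so a build-and-train run is
reproducible on the same machine. Bit-level equality across BLAS
implementations is not promised; tests compare behaviour, not bits.

## Event scoring

The output trace is thresholded at 0.5 (inclusive). Every maximal run of
ones — in labels or output, regardless of length — is one event. A
predicted event matches a label event when their ranges overlap by at
least one sample (`min_overlap`, configurable); matching is one-to-one.
Matched pairs are TP, unmatched predictions FP, unmatched labels FN, and
TN is the count of samples covered by neither mask divided by the
5-sample event duration (time normalization; TN enters no reported
metric). Precision, recall and F are the usual

$$P = \frac{TP}{TP+FP}, \qquad R = \frac{TP}{TP+FN}, \qquad
F = \frac{2PR}{P+R},$$

with two documented degenerate conventions: a window with no events and no
detections scores $P=R=F=1$ (perfect silence), and $TP=0$ with any error
scores $F=0$.

One implementation note on matching. Resolving overlaps greedily by
descending overlap is intuitive but not optimal: with events
$P_1=[0,10)$, $P_2=[10,30)$ against labels $L_1=[5,25)$, $L_2=[25,40)$,
greedy pairs $P_2$ with $L_1$ (overlap 15) and strands both $P_1$ and
$L_2$, scoring one TP where two are attainable. Because predicted events
are disjoint and sorted, and label events likewise, crossing matches are
geometrically impossible, so a standard alignment dynamic program over the
two sorted lists — maximizing match count, then total overlap — computes
the *exact* optimum in $O(nm)$. That DP is the implementation, and the
test suite holds it equal to a brute-force enumeration of all one-to-one
matchings on a thousand random windows.

## Evaluation scenarios

Three protocols, matching how such a detector would actually be deployed:

* **pooled** — one stratified-by-(subject, condition) 80/20 window split,
  one model: the upper envelope of performance;
* **loso** — leave-one-subject-out: train on all subjects but one, test on
  the held-out subject; the realistic "new user" setting;
* **per_subject** — train and test within each subject's own data only;
  small-sample behaviour.

Splits use per-stratum `floor(0.8 n)` rounding and recorded seeds; 10% of
each training fraction is carved off (same stratification) for early
stopping. Per-fold rows report each condition plus an "all contexts" row
that pools confusion counts by default (averaging per-condition F instead
is a flag, since either reading of "overall" is defensible). Median and
mean F per condition are reported across folds, and a condition absent
from a fold yields an explicit NA row that aggregates skip.

## The synthetic cohort

The subjects recorded for the motivating study are not public, so the
package ships a simulator whose output stands in for them everywhere —
tests, examples, and the acceptance script. It emulates three recording
conditions: quiet standing (**rest**), a held contraction (**static**),
and repetitive exercise (**dynamic**).

The cardiac component is a train of biphasic QRS-like templates — the
negated second derivative of a Gaussian, 80 ms wide, apex amplitude 1 —
placed at beat times whose intervals are Gaussian around 0.8 s (SD
0.05 s) with 5% sinusoidal modulation at 0.25 Hz emulating respiratory
sinus arrhythmia, and an optional per-beat ectopy mechanism (0.6×
premature interval, compensatory 1.3× pause). The muscle component is
band-limited Gaussian noise (20–150 Hz, 4th-order zero-phase Butterworth)
scaled to a target RMS and shaped by a condition envelope: flat at rest;
slow ±20% drift at 0.5 Hz for static hold; raised-cosine bursts at 0.5 Hz
with 50% duty for dynamic repetitions. Default noise RMS values relative
to the unit R-wave are 0.1 / 0.5 / 1.0 for rest / static / dynamic —
chosen once so that rest is nearly clean, static is a moderate sustained
contamination, and dynamic bursts rival the R-wave. These are simulator
conventions, not measurements of any hardware; no quantitative SNR for
the real recording conditions is available to calibrate against.

A simulated cohort perturbs each subject's R-wave amplitude and noise RMS
by ±20%, which is the minimum heterogeneity that makes leave-one-subject-
out a real generalization test rather than a relabeled random split.
Default recordings are 40 s (within the 13 s–1.5 min range typical of
exercise sets), six subjects, one recording per condition.

What the simulator deliberately does *not* model: P and T waves, electrode
motion artifacts, baseline wander, powerline interference, or the true
spectral shape of contracting muscle. Passing tests on this cohort
therefore demonstrate that the pipeline — labeling, training, event
scoring, rhythm reconstruction — behaves as designed under controlled
contamination; they do not certify performance on any particular device's
recordings.

## Rhythmogram and HRV

Detected apexes are lifted to global sample indices, converted to seconds,
and de-duplicated with a 0.2 s refractory merge (two detections closer
than 300 bpm allows are one beat; the stronger response wins). Successive
differences give the R-R series; SDNN and RMSSD follow their standard
definitions. Tachycardia/bradycardia flags mark every maximal run of at
least 3 consecutive intervals with instantaneous rate above 100 or below
60 bpm — conventional clinical cutoffs, all configurable, since the
motivating use case names the screening task but no thresholds.

## Numerical choices and edge cases

* Constant (flat) traces normalize to all zeros rather than dividing by a
  zero range; a flat trace carries no events.
* `binarize` treats exactly 0.5 as belonging to an R-wave (inclusive
  boundary).
* Apexes of even-length predicted runs take the run's argmax when the
  trace is supplied, first index on ties; midpoint otherwise.
* Interval draws are floored at 0.25 of the mean R-R so beat times remain
  strictly increasing under extreme jitter.
* An untrained model refuses `predict()` unless explicitly allowed
  (`allow_untrained = TRUE`), which keeps accidental use of random
  weights loud while letting robustness paths (e.g. recovery reports) run.

## Problem sizes used in tests

Unit tests run miniature versions of everything: 128-sample windows,
two-layer encoders, cohorts of 2–4 subjects and a few seconds of signal,
so the whole non-acceptance suite completes in well under a minute. The
end-to-end checks train the default 1600-sample architecture on 6-subject
cohorts of 40 s recordings with a 30-epoch budget (patience 8) — the point
where the rest-condition task has long converged — rather than the
200-epoch default budget, which is sized for harder real recordings.
These sizes are the package's own desk-scale choices and are stated here
so that they are not mistaken for claims about the original study's
training regime.

## Known limitations

* The simulator's noise is stationary Gaussian within its envelope; real
  EMG is impulsive and its spectrum shifts with load.
* Training is single-threaded CPU code; it is sized for desk-scale
  experiments, not for large corpora.
* High-intensity contraction of the instrumented muscle itself (noise RMS
  well above the R-wave) is out of the detector's design envelope, as the
  dynamic-condition scores show.
* No frequency-domain or nonlinear HRV indices; the rhythmogram module
  stops at time-domain statistics and threshold screening.

## A worked end-to-end run

```{r example, eval = FALSE}
cohort <- simulate_cohort(6, 1, sim_config(seed = 1))
report <- run_scenario(cohort, "pooled",
                       model_config(max_epochs = 30,
                                    early_stop_patience = 8),
                       split_seed = 1)
tidy(report)      # per-condition confusion counts and P/R/F
glance(report)    # one wide row of median F per condition
autoplot(report)  # per-fold F by condition

# rhythm recovery against ground truth on a clean recording
rec <- simulate_recording(sim_config(seed = 99, emg_rms = 0))
# det: a trained detector from train_detector() or load_detector()
# recover_rr(det, rec)$matched_fraction
```

The README shows the numbers such a run actually printed;
`scripts/acceptance.R` recomputes them from scratch under any seed. The
vignette states no empirical result that the tests or that script do not
themselves compute.
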