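# rwavenet

Heart rhythm from a chest-worn EMG channel. Surface electrodes over the
pectoral muscles record a superposition of skeletal-muscle activity and
the heart's electrical signal; the R-wave of each QRS complex survives in
the mixture. `rwavenet` extracts those R-waves with a supervised 1-D
convolutional autoencoder, scores detections with an event-based
precision/recall/F protocol under three cross-validation scenarios, and
turns detected beats into a rhythmogram (R–R interval series) with
time-domain HRV statistics and tachycardia/bradycardia flags.

The package is aimed at physiological-signal researchers who want a
transparent, fully testable reference pipeline for cardiac-component
extraction from contaminated biosignals. Because no suitable public
recordings exist, it ships a seeded EMG+ECG mixture simulator with known
ground truth: every stage — labeling, training, event matching, rhythm
reconstruction — is exercised end to end on synthetic cohorts.

## The method in brief

A recording (500 Hz, single channel) is min-max normalized to [−1, 1] and
cut into 1600-sample windows. Each annotated R-apex labels five
consecutive mask samples centered on the apex. The detector is an
encoder–decoder convolutional network — encoder `(9,16,2) (9,32,2)
(5,64,2)` (kernel, filters, stride) with batch normalization, bottleneck
dropout 0.3, mirrored transposed-convolution decoder, sigmoid output —
trained with positive-weighted binary cross-entropy (Adam, early
stopping). Output traces are thresholded at 0.5; maximal runs of ones are
events. A predicted event matching a label event (≥ 1 sample overlap,
one-to-one, optimal assignment) is a TP; precision, recall and

&nbsp;&nbsp;&nbsp;&nbsp;P = TP/(TP+FP),&nbsp;&nbsp; R = TP/(TP+FN),&nbsp;&nbsp; F = 2PR/(P+R)

summarize each scenario: **pooled** (stratified 80/20 split over all
subjects), **loso** (leave-one-subject-out), **per_subject** (within-
subject 80/20). The network and its gradients are implemented in the
package itself (RcppArmadillo); a finite-difference gradient check in the
test suite is the correctness oracle.

## Worked example

```r
library(rwavenet)

# a 6-subject synthetic cohort: rest / static / dynamic conditions
cohort <- simulate_cohort(6, 1, sim_config(seed = 1))

# pooled scenario: one stratified 80/20 split, one model
report <- run_scenario(cohort, "pooled",
                       model_config(max_epochs = 30,
                                    early_stop_patience = 8),
                       split_seed = 1)
tidy(report)[, c("condition", "tp", "fp", "fn", "precision",
                 "recall", "f_measure")]
#> # A tibble: 4 × 7
#>   condition    tp    fp    fn precision recall f_measure
#>   <chr>     <int> <int> <int>     <dbl>  <dbl>     <dbl>
#> 1 rest         70     1     0     0.986  1         0.993
#> 2 static       72     4     0     0.947  1         0.973
#> 3 dynamic      69     3     1     0.958  0.986     0.972
#> 4 all         211     8     1     0.963  0.995     0.979
```

Per condition: `tp`/`fp`/`fn` are matched, spurious and missed beat
events in the 20% test windows; detection is near-perfect at rest and
degrades mildly under contraction noise — the qualitative ordering the
detector is designed around. Rhythm recovery on a fresh clean recording:

```r
det <- # train on noise-free windows as in scripts/acceptance.R
recovery <- recover_rr(det, simulate_recording(sim_config(seed = 2001,
                                                          emg_rms = 0)))
recovery$matched_fraction       # 1     : every true beat found
autoplot(recovery$rhythmogram)  # tachogram of R-R intervals
```

A command-line pipeline (`simulate`, `preprocess`, `train`, `detect`,
`evaluate`, `hrv`) is available via
`system.file("cli", "rwavenet", package = "rwavenet")`; see
`?cli_main`.

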