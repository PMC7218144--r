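---
title: "Methods: hybrid time-frequency networks for ECoG language mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid time-frequency networks for ECoG language mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During pre-surgical evaluation of drug-resistant epilepsy, subdural electrode
grids record electrocorticography (ECoG) directly from the cortical surface.
Before resection, the surgical team must know which electrodes overlie
*eloquent* (here: language-critical) cortex.  The gold standard,
electro-cortical stimulation mapping (ESM), carries a risk of provoked
seizures, which motivates passive, task-based alternatives: ECoG functional
mapping (ECoG-FM) infers each electrode's status from its signal during a
language task.

`ecogmapr` implements a learned ECoG-FM pipeline.  Each channel is classified
as a **positive response channel (PRC)** — language-involved cortex — or a
**negative response channel (NRC)**, with ESM-derived labels as ground truth
during training.  Two properties distinguish the approach from the
conventional band-power baseline:

* channels are compared **against other channels**, not against their own
  resting baseline, and
* the **full spectrum** is used, not only the high-gamma (70–170 Hz) band
  where task-related power changes are conventionally sought.

## Task paradigm and data model

The recording paradigm alternates ten 30 s blocks at 1200 Hz: five *control*
blocks (listening to broadband noise) interleaved with five *active* blocks
(story listening, a different story per block).  A channel's recording is
held as an `ecog_recording`: the continuous signal, the sampling rate, a
block annotation table (0-based, half-open sample intervals), and the
optional truth label.  Annotations live in a JSON sidecar next to the signal
file (CSV or EDF), so plain-text fixtures are first class; amplitudes are
never rescaled implicitly because variance-sensitive features (Hjorth
activity) depend on the scale.

The five processing stages are:

1. **Segmentation** — `trim_to_task()` discards pre/post-task signal;
   `extract_blocks()` cuts uniform blocks (`round(30 * fs)` samples each and
   validated as such); `sliding_windows()` slices a block into overlapping
   sub-block windows of 600 samples (0.5 s) every 100 samples, giving
   `floor((L - width)/stride) + 1 = 355` windows per 36,000-sample block.
   Windows never straddle block boundaries and are dropped, not padded, at
   the block edge.
2. **Time-domain features** — per window: mean, skewness, excess kurtosis,
   peak-to-peak, and the Hjorth trio (activity = population variance,
   mobility = `sqrt(var(diff x)/var x)`, complexity = mobility of the
   differenced signal over mobility).  The window-by-feature matrix of one
   block is a *sub-block stream*, the sequence the time-domain network
   consumes.
3. **Frequency-domain features** — an autoregressive model
   `x[n] = -sum_k a[k] x[n-k] + w[n]` fitted per block by Burg
   reflection-coefficient estimation (`fit_ar_reflection()`); the
   coefficients `a[1..p]` are the frequency feature vector.
4. **Networks** — the variant zoo (below) maps a sub-block stream (and,
   for hybrid variants, the block's AR vector) to a PRC probability via a
   sigmoid head; an instance is labelled positive iff its probability
   strictly exceeds 0.5.
5. **Majority voting** — a channel is PRC if strictly more than half of its
   active-block instances vote positive, NRC if strictly fewer, and receives
   no label on an exact tie (abstentions are counted and reported, never
   silently resolved).

### What counts as a "sub-block"

The classified instance is one active block's full window-feature sequence
(355 × n_features at the default geometry), labelled with its channel's
status.  Finer instance granularities are conceivable — the term sub-block is
used in the field for any overlapping segment — but the per-block stream is
the shape the sequence models need, keeps one AR vector attached to exactly
one instance, and makes the vote an odd-sized poll over the five stories (so
ties cannot occur at the default paradigm; the tie rule still exists for
other configurations).

## The architecture family

All variants share three building blocks: a stack of 1D convolutions over
the window axis (ReLU, 'same' padding) followed by global average pooling;
an LSTM path whose final hidden state summarises the sequence; and a
fully connected frequency module over the AR vector.  Fusion is always
**concatenation** along the feature axis — never stacking or element-wise
product, which would force the two domains to share a dimension.

| variant | time path | frequency path | fusion head |
|---|---|---|---|
| `AT1` | conv + GAP | — | dense sigmoid |
| `AT2` | conv + GAP, LSTM | — | dense sigmoid |
| `AT_AR1` | conv + GAP, LSTM | 1 FC | concat → sigmoid |
| `AT_AR2` | conv sequence (+ LSTM at head) | 1 FC, tiled along time | 1D convs → GAP → sigmoid |
| `AT_AR3` | conv + GAP, LSTM | 1 FC | FC → sigmoid |
| `AT_AR4` | conv + GAP, LSTM | 2 FC | FC → sigmoid |
| `AT_AR3_EF` | as `AT_AR3`, features as input channels | shared | FC → sigmoid |
| `AT_AR3_LF1` | one trunk per feature | one shared FC | concat all → FC → sigmoid |
| `AT_AR3_LF2` | one trunk per feature | merged into every per-feature branch before fusion | FC → sigmoid |
| `PER_STORY` | one `AT_AR3` trunk per story | per story | concat story branches → FC → sigmoid |

The *control-task* twins (CT-AR²/CT-AR³) are not separate architectures:
setting `condition = "control"` in `experiment_config()` feeds the same
models control-block streams, which is exactly how the twins are defined.

Because no deep-learning framework ships with the scientific R stack, the
training engine is authored in-package: a small reverse-mode tape over dense,
convolution (im2col + BLAS), pooling, concatenation and dropout ops, with the
LSTM recurrence compiled via RcppArmadillo.  Gradients of every variant are
verified against central finite differences in the test suite.  Training
minimises binary cross-entropy with Adam (default learning rate `1e-3`,
batch 32), stopping early when the monitored loss has not improved for
`patience` epochs and restoring the best weights.  With a fixed seed the run
is deterministic, and identical inputs always produce identical predictions.

### Layer sizes

The layer hyperparameters are free parameters of this implementation (the
architecture family, not any particular width, is the method).  Defaults are
sized for cohorts of tens of channels — conv filters 16/32/16 with kernels
8/5/3 (the classic fully-convolutional time-series profile), 16 LSTM units,
32-unit fusion layer, dropout 0.2 — and everything is overridable through
`model_spec(hyper = ...)`.  With hundreds of clinical channels one would
scale these up; none of the package's validation results depend on the exact
values.

### Normalisation

Whether and how features were normalised is left open in descriptions of
this kind of pipeline; here every feature column (and every AR coefficient
dimension) is z-scored with statistics computed **from the training fold
only** and stored inside the trained model, so validation and test data can
never leak into the scaling.

## Evaluation protocol

Negative channels outnumber positives roughly 3:1, so `balance_classes()`
undersamples NRCs to a 1:1 ratio — re-drawn per repeat with a derived seed,
so the subsample variability is averaged over rather than frozen.
`grouped_shuffle_split()` repeatedly holds out a stratified fraction
(default 0.2, at least one channel per class) of **whole channels**: every
sub-block of a channel travels with it, so no channel contributes to both
training and testing in any repeat.  The default is 30 repeats.

Metrics are computed at two levels: *block accuracy* is the instance-level
correct fraction before voting; sensitivity, specificity and accuracy are
channel-level after voting, with abstaining channels excluded from the
denominators and reported separately.  Per-repeat values are summarised as
mean ± sd, mirroring the familiar results-table layout
(`write_results_table()`).

Training paradigm I trains on a single hand-crafted feature (mobility by
default); paradigm II fuses the quartet mobility/skew/mean/peak-to-peak
either as input channels (early fusion) or through per-feature sub-models
(late fusion); paradigm III trains one trunk per story and merges through a
final fully connected layer, yielding one merged prediction per channel
(votes over one instance reduce to that instance's label).

## The synthetic cohort generator

Clinical ECoG with ESM labels is not publicly distributable, so
`generate_cohort()` produces the cohorts every end-to-end test runs on.  It
emulates exactly the statistical structure the pipeline assumes:

* ten alternating 30 s blocks at 1200 Hz, control first, stories 1–5 on the
  active blocks;
* a stationary colored-noise baseline per channel — an AR(1) process
  (default pole 0.95) whose low-pass spectrum stands in for the 1/f-like
  broadband background — with per-channel pole and gain jitter so that
  cross-channel normalisation is actually exercised;
* PRC active blocks receive additive band-limited noise
  (Butterworth-filtered, default 70–170 Hz) scaled so the block's band power
  is `effect_gain` times the baseline band power, with per-story amplitude
  jitter (so paradigm III has structure to exploit); NRC active blocks are
  statistically identical to control blocks;
* `power_neutral = TRUE` rescales boosted blocks to their own pre-boost
  variance, confining the class signal to the spectral *shape* — the regime
  used to demonstrate that the hybrid model beats the time-only model when
  the discriminative information is purely spectral;
* everything is bit-deterministic in the seed, with per-channel seeds
  derived from the cohort seed.

`band_power_summary()` (Welch periodogram band integrals) and
`conventional_detector()` (one-sided rank-sum of active vs control band
power) provide the classical within-channel baseline view, used both to
validate the generator and as the comparison method the learned pipeline is
meant to surpass.

What the generator does **not** emulate: volume conduction and montage
effects, movement or line-noise artifacts, non-stationary drift within
blocks, inter-patient covariate shift, and any realistic relationship
between electrode position and response. A pipeline that passes on this
generator is validated as *mechanically correct and able to recover a known
band-power contrast at realistic sampling geometry* — not as clinically
accurate; the clinical effect size is unknowable from published summaries,
and `effect_gain` is a calibration knob, not an estimate of it.

## Numerical choices

* Moment features use population (1/N) estimators, skewness/kurtosis in the
  plain moment form (excess kurtosis); zero-variance windows return 0 for
  both by convention, while zero-variance input to the Hjorth trio is a
  degenerate-input error (callers may skip or fill such windows —
  `build_feature_sequence(degenerate=)`).
* Hjorth derivatives are first differences without sampling-rate scaling:
  mobility is used as a relative feature and the constant cancels in
  complexity.
* Burg fitting demeans by default (the AR model assumes a zero-mean
  process); the sign convention puts the AR polynomial on the left
  (`a[1] = -0.9` for a process with lag-1 coefficient 0.9), and
  `ar_conventional()` converts to the regression convention for interop.
  Reflection coefficients are bounded by 1 in magnitude by construction and
  the prediction-error power is non-increasing in the order, both asserted
  in tests.
* AR features are fitted per 30 s block, not per 600-sample window: an
  order-20 fit on 600 samples would be noise-dominated, and the fusion
  architectures take a single frequency vector per classified instance.
  Order 20 is the default; AIC/FPE selection over the Burg error-power path
  is available (`select_ar_order()`), since the order is a configuration
  choice rather than a published constant.
* The sigmoid threshold is fixed at 0.5 (strict inequality; exactly 0.5 is
  negative).  Class imbalance is handled by undersampling, never by
  threshold tuning.

## Problem sizes used in validation

The shipped validation runs are sized for a workstation: cohorts of 40–80
channels at the full 1200 Hz/30 s geometry for the end-to-end checks (null
calibration at `effect_gain = 1`, label recovery at `effect_gain = 4`,
fusion-vs-time-only comparison on power-neutral cohorts), 5–10 repeats per
experiment, and reduced layer widths.  Unit tests use a miniature paradigm
(600 Hz, 2 s blocks) that keeps every contract intact at a fraction of the
cost.

## Known limitations

* The per-block instance definition gives five votes per channel at the
  default paradigm; abstentions only become possible for even vote counts.
* The EDF writer/reader covers the equal-rate continuous subset of the
  format (16-bit records, no embedded annotations); HDF5 is not supported.
* Single-threaded training in R/RcppArmadillo is adequate for tens of
  channels; clinical-scale cohorts (hundreds of channels, wide layers) would
  want a GPU framework behind the same interfaces.
* Patient-wise (leave-one-subject-out) evaluation is out of scope: the
  grouping unit is the channel.
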