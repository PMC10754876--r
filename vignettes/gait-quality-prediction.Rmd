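---
title: "Predicting gait-quality progression: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gait-quality progression: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcast)
```

## The problem

Clinical three-dimensional gait analysis summarizes how a patient walks as a
set of *gait cycles*: one stride each, time-normalized to 101 samples
(0--100% of the stride) of nine joint-angle curves in degrees (three pelvic
angles, three hip angles, knee flexion/extension, ankle
plantar/dorsiflexion, foot progression). A session in the motion laboratory
yields a few dozen such cycles. The clinical question `gaitcast` addresses
is prognostic: given the cycles of the current session, will the patient's
gait quality have improved or worsened by the next visit?

## Gait quality scores

Gait quality is quantified against a normative reference (mean curves of a
typically developing population). For angle $n$, the Gait Variable Score is
the RMS deviation over the cycle,

$$\mathrm{GVS}_n \;=\; \sqrt{\tfrac{1}{T}\textstyle\sum_{t=1}^{T}
\big(c_{t,n}-c^{\mathrm{ref}}_{t,n}\big)^2},\qquad T = 101,$$

and the Gait Profile Score is the RMS of the nine GVS values,
$\mathrm{GPS} = \sqrt{\tfrac{1}{N}\sum_n \mathrm{GVS}_n^2}$, $N = 9$, a
single gait-quality index in degrees. The divisor is $T$, not $T-1$: the
score is a population RMS, not a sample standard deviation. Both are exposed
by `gvs()`, `gps()` and `map_profile()`; tests pin them to an independent
double-loop summation at $10^{-12}$ relative tolerance.

## The prediction target

For consecutive sessions $(E_{p,d}, E_{p,d+\Delta d})$ of the same patient,
each cycle $C$ of the *current* session receives the signed change

$$\Delta\mathrm{GPS}(C) \;=\;
\mathrm{GPS}_{avg}(E_{p,d+\Delta d}) - \mathrm{GPS}(C),$$

where the first term is the mean per-cycle GPS of the next session. A
negative change means the gait improves (class 1), a positive one that it
worsens (class 0). An exactly zero change is classed 0 ("not improved") — a
measure-zero tie that needs a fixed rule for deterministic tests. Only pairs
in which both sessions were walked without equipment are labeled, so the two
sessions are compared under the same condition.

Splits are assigned per *patient*, never per cycle or per pair: cycles of
one patient are strongly correlated, and patient-level grouping prevents
leakage between training and evaluation. The split targets fractions of
total cycles (defaults re-normalize the published 73/12/14 split) using a
greedy largest-first assignment with a seeded shuffle for tie-breaking.

## Signal-based and image-based classifiers

Two input encodings feed binary classifiers that all end in a single
sigmoid unit trained with Adam and binary cross-entropy:

* **Signal models** consume the raw `101 x 9` cycle (the MLP takes the
  time-major flattened 909-sample vector): a tuned MLP (4 hidden layers of
  200), a stacked LSTM (4 layers of 500 units, dropout before the output),
  and the reference time-series-classification designs FCN (convolutions
  128/256/128 with kernels 8/5/3, batch norm, global average pooling),
  1D ResNet (three residual blocks), Encoder (convolutions 128/256/512 with
  kernels 5/11/21, instance norm, PReLU, attention pooling), t-LeNet, and an
  encoder-only Transformer (4 blocks, 4 heads, width 64 — defaults chosen
  here, as only an existing implementation is cited for this design).
* **Image models** consume the centralized 2D-FFT magnitude of the cycle,
  $|F(u,v)|$ with overall scaling $1/(T\cdot N)$ and the DC bin shifted to
  the image center (0-based index (50, 4)). The printed summation bounds of
  the transform would imply $T+1$ and $N+1$ points; the implementation uses
  the standard DFT over $t = 0..T-1$, $n = 0..N-1$, keeping the printed
  scaling. The compact "tailored" CNN (2 same-padded 32 x 32 convolutions of
  4 filters, dropout 0, 8 x 8 max pooling, batch norm, a 300-unit dense
  layer) consumes the untiled `101 x 9` spectrum — the geometry under which
  its published parameter count (35,505 including normalization running
  statistics) is reproduced exactly, with non-overlapping floor-division
  pooling leaving a 12 x 1 x 4 map, i.e. 48 flattened features. Large
  pretrained-style backbones (VGG16, ResNet34, EfficientNet-B0, ViT-B/16)
  require at least 32-pixel-wide inputs, so the 9-column spectrum is tiled
  four times to `101 x 36`.

The backbones are represented as exact per-layer parameter inventories
(first layer adapted to one input channel, head replaced by one unit) rather
than materialized weight tensors: no pretrained weights are shipped or
downloaded, and their role in the package is architecture inspection and
parameter accounting. Two counting conventions are implemented because
published per-model counts mix two frameworks' reporting styles:
`learnable_only` (matches the VGG16/ResNet34/EfficientNet-B0 counts) and
`learnable_plus_norm_stats` (matches the tailored CNN's count). The printed
ViT count is not reconcilable with a standard ViT-B/16 under either
convention by independent arithmetic (85,406,209 vs 85,260,289 printed), so
the ViT is built but its count is not pinned.

Whether hidden MLP layers use ReLU and dropout is not specified anywhere;
ReLU without hidden dropout is used. Spectrum images are standardized with
the training-set mean and standard deviation before entering image models —
a choice the source material leaves open; magnitude (not log-magnitude, not
phase) is the model input.

## The neural-network engine

No deep-learning framework is used: the package carries a self-contained
engine on base R matrix algebra. Dense layers, 1D convolutions (im2col),
batch normalization, pooling, dropout, global average pooling and residual
blocks implement both forward and backward passes; gradients are verified
against central finite differences in the test suite. The 2D convolution is
evaluated in the frequency domain: zero-padded to $(H+k_h-1)\times(W+k_w-1)$,
circular correlation via the FFT equals linear correlation on the valid
region, so the forward pass, the weight gradient and the input gradient each
cost a handful of FFTs per sample — exact to rounding and far cheaper than
im2col for the 32 x 32 kernels of the spectrum CNN. LSTM, Encoder
(instance norm, PReLU, attention) and Transformer layers implement forward
passes only; the training-dependent property suites train the
dense/convolutional family (MLP, FCN, t-LeNet, 1D ResNet, tailored CNN),
which is where gradient support matters. Training uses Adam with binary
cross-entropy, per-epoch validation AUC, early stopping and restoration of
the best-validation weights; the "epoch of convergence" is the argmax
epoch. All randomness (weight init, shuffling, dropout, augmentation) flows
through seeded streams isolated from the caller's RNG, so a run is
bit-reproducible from its configuration.

## Data augmentation

Five classical time-series augmentation operators are applied to training
batches only: jittering (additive Gaussian noise), scaling (one
multiplicative factor per angle), window warping (a random window
stretched/compressed and the series resampled to 101 points), permutation
(contiguous near-equal segments shuffled; the first `101 mod k` segments
take the extra point), and window slicing (a random crop resampled back to
101 — re-interpolation keeps a fixed input length for every model, which the
source leaves open). The application *order* is drawn once per batch;
each example draws its own operator randomness. Published hyperparameter
values are not available ("empirically optimized"); the defaults
(`jitter_sigma` 0.5 deg, `scale_sigma` 0.1, warp ratio 0.1 with factors
{0.5, 2}, 4 segments, slice ratio 0.9) are conventional values from the
time-series-augmentation literature and are all exposed in
`augmentation_config()`.

## Evaluation

`auc_mw()` is the Mann-Whitney AUC (ties count one half); `roc_points()`
returns the threshold curve whose trapezoidal area equals it exactly.
`delong_test()` compares two correlated ROC curves through per-example
structural components; its variance is checked against a bootstrap and its
null p-values for calibration, and both AUC and test are cross-checked
against the independent pROC implementation in the test suite.

## The synthetic cohort generator

The clinical database the method was developed on is private, so the
package ships a generator that emulates the *structure* the analysis relies
on, with planted ground truth:

* The normative reference and each patient's deviation *shape* are smooth
  curves of at most four Fourier harmonics with physiological magnitudes
  (e.g. knee flexion excursions near 60 degrees).
* A patient's deviation shape is normalized so its GPS against the
  reference is exactly 1; cycles are
  `reference + severity x shape + noise`. The scale property of the GPS
  then makes planted severity equal expected GPS — the analytic hook most
  generator tests use.
* Severity evolves multiplicatively between sessions: improvement divides
  by a factor drawn log-uniformly from [1.1, 1.6], worsening multiplies.
  Session counts (1 + Poisson(1), at most 5), cycles per session
  (Normal(18, 6^2) rounded and clipped to [5, 40]), the equipment-free
  share (0.79) and inter-session gaps (Normal(740, 577^2) days, at least 4)
  mirror the published descriptive statistics of the clinical database.
* `improve_rule` selects what drives the direction: `"random"` (a fair
  coin per transition — a *null* cohort: nothing observable predicts the
  label) or `"severity_threshold"` (improvement iff current severity
  exceeds the midpoint of the severity range — a regression-to-threshold
  cohort whose labels are predictable from the observable deviation
  magnitude). The rule exists because a coin-flip progression is, by
  construction, unlearnable from the current cycles; the threshold rule is
  the "strong planted signal" condition used by the end-to-end learning
  checks.

What the generator does **not** emulate: real pathology-specific deviation
patterns, age structure, left/right asymmetries, marker noise, or
correlations between equipment use and severity. Passing the end-to-end
checks therefore demonstrates that the pipeline's plumbing, scores, labels
and models behave correctly and can learn a deviation-magnitude signal —
not that the published clinical AUCs (≈ 0.72) are reproduced; those were
measured on the private cohort and are out of reach of any synthetic
stand-in.

## Problem sizes and numerical choices

The shipped checks choose sizes that keep the full suite in the
tens-of-minutes range on a single core: the planted-cohort learning check
uses 100 patients with the generator defaults; the null-cohort check uses
600 patients with a test-heavy split (25/5/70) and caps training at 512
cycles. The null check is evaluated on several hundred session *pairs*
because labels and scores cluster within a pair, so the chance-level AUC
concentrates with the number of pairs, not cycles; with ~400 test pairs the
[0.4, 0.6] band is a ±2 SD statement. Training for these checks runs at
most 6–8 epochs with early stopping patience 2–3 — the planted signal is
near-separable and both models converge within the first epochs.

Other numerical choices: linear interpolation for time normalization (no
extrapolation; endpoints preserved); angle validity screened at ±360
degrees (a loose sanity bound, not physiology); batch norm momentum 0.9 and
epsilon 1e-5; accuracy threshold fixed at 0.5; DeLong's test applied to
test-set scores; a degenerate DeLong comparison (identical scores) returns
p = 1 by definition. Default training configuration: learning rate 1e-3,
batch size 64, up to 1000 epochs with patience 50 (the learning rate
4.127e-4 tuned for the spectrum CNN is retained as that model's
documented value).

## Known limitations

* LSTM, Encoder and Transformer are inference-only in this version.
* The large 2D backbones are parameter inventories, not trainable tensors;
  fine-tuning them is out of scope.
* A single normative reference is used (no age stratification).
* Regression on the continuous GPS change, multi-class severity grading and
  per-pathology stratification are out of scope.
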