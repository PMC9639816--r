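---
title: "Multi-stream feature fusion for sEMG gesture recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stream feature fusion for sEMG gesture recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(semgfusion)
```

## The problem

Surface electromyography (sEMG) records the electrical activity of skeletal
muscle from electrodes on the skin.  In the intrasubject gesture-recognition
setting a subject performs a protocol of hand/wrist gestures — in the
NinaPro-style acquisitions this package targets, each gesture is repeated six
times, five seconds of movement alternating with three seconds of rest,
recorded by 12 electrodes at 2000 Hz — and a classifier is trained on some
repetitions and tested on held-out repetitions of the *same* subject.  The
12 electrodes are not interchangeable: eight form a ring around the forearm,
two sit on the flexor/extensor digitorum, and two on the biceps/triceps.
The network exploits this grouping directly.

## Pipeline

1. **Denoising.**  A fourth-order Butterworth band-pass (10–500 Hz, the band
   carrying essentially all sEMG energy) is applied zero-phase
   (forward–backward).  The pipeline is offline, so zero-phase
   filtering was chosen over causal filtering: it avoids phase distortion at
   the cost of the squared magnitude response, and our tests compare against
   the analytic response accordingly.  No signal-processing library exists in
   the target environment, so the design (analog prototype, low-pass to
   band-pass transform, bilinear transform with pre-warping) is implemented
   from first principles and cross-checked against `scipy.signal.butter` to
   about 1e-10.

2. **Action segmentation.**  Each maximal run of a constant nonzero label on
   the chosen label track (`stimulus` = prompted labels, `restimulus` =
   posterior movement-refined labels) becomes one gesture segment; rest
   separates gestures.  A 49-class, 6-repetition protocol therefore yields
   exactly 294 segments.  A segment's repetition index is the majority value
   of the repetition track over the run — robust to the inward boundary
   jitter of posterior labels.

3. **Z-score normalisation**, `y = (x - mu) / sigma` per electrode channel
   with population statistics.  The fit population is deliberately the
   concatenated *training-repetition* data of the subject, applied to all of
   that subject's data: the reference design leaves the fit population
   under-specified, and fitting on the training side only is the choice
   that cannot leak test data.  Whether standardisation happens before or
   after segmentation is equally open; we standardise after segmentation (the segment rows are
   exact slices of the recording, so the two orders differ only in whether
   rest samples enter the statistics).

4. **Fragmentation.**  Sliding windows of 200 ms advanced by 50 ms — 400 ×
   12 samples at 2000 Hz — cut strictly inside each segment, so no window
   ever spans two gestures.  For a segment of `L` samples the count is
   `floor((L - W)/S) + 1`.  Windows are aligned to the segment start
   (offset 0); no offset convention is prescribed by the reference design.

5. **Split.**  Repetitions 1, 3, 4, 6 train; 2, 5 test.  Repeated-gesture
   cross-validation builds four folds, fold *i* holding out the *i*-th
   training repetition for validation.

## Time-warping augmentation

Training segments are doubled by time warping before fragmentation.  The
reference design names two control knobs — the number of speed changes and the
maximum/minimum speed ratio — but no construction, so the package uses the
simplest construction honouring both: split the time axis into
`n_speed_changes + 1` equal bins, draw one speed per bin uniformly from
`[1, max_speed_ratio]` (shuffled so the fastest bin is random), integrate to
a cumulative map and renormalise to fixed endpoints.  The map is strictly
increasing by construction, is applied identically to all channels by linear
interpolation (preserving inter-channel synchronisation and amplitude), and
`max_speed_ratio = 1` gives the identity.  Knob defaults (4 changes, ratio
2.0) are package decisions, exposed in `warp_config()`.  Warped copies join
the training side of every fold but never the validation side, since
validating on synthetic variants would flatter the model.

## The network

Each 400 × 12 × 1 fragment is treated as a single-channel image and split
along the electrode axis into three streams (8, 2, 2).  Per stream:

* **BConv1**: 64 filters of kernel 8×1 (8 time samples of one electrode —
  signal morphology), then ReLU, then batch normalisation.  The
  convolution → ReLU → BN order follows the reference design's ablation
  finding that BN after the activation beats the conventional order.
* **Residual attention** (ResCBAM): channel attention first, spatial
  attention second, and the *original* block input added back:
  `out = F + SAS(CAS(F) * F) * (CAS(F) * F)`.  With both attention maps at
  `sigmoid(0) = 0.5` and constant input this is exactly `1.25 * F` — the
  branch can never die, which the tests assert.
* **BConv2**: 128 filters of kernel 1×8 (stream 1) or 1×2 (the 2-electrode
  streams; a 1×8 kernel cannot apply to a 2-wide electrode axis), ReLU, BN,
  followed by a second residual attention block.

The per-stream interleaving BConv1 → ResCBAM → BConv2 → ResCBAM is the
minimal arrangement consistent with the reference layer table (attention
input of 64 channels) and the 128-channel late-fusion width; the exact
count/placement is never printed there, which we flag as an open point.

**Fusion and head.**  Late fusion concatenates the three stream outputs
along the electrode axis (400 × 12 × 128).  Early fusion expands the raw,
un-split fragment with 32 linear 1×1 convolutions (400 × 12 × 32; no
activation — unstated in the reference design, and a linear projection keeps the branch
an identity-like shortcut).  Channel concatenation gives 400 × 12 × 160,
global average pooling reduces each channel to one neuron (length-160
vector), and a 512-wide fully connected layer with ReLU, dropout 0.5, and a
softmax output layer produce the class distribution.  The reference design
prints the pooled tensor as 400 × 160 while describing one output neuron
per feature channel; we follow the description and pool over both spatial
axes, treating the printed shape as a typo.  FC width and dropout rate are unstated; 512 and 0.5 are
configurable defaults.

**Attention details.**  Channel attention pools over space with average and
max pooling, pushes both descriptors through one shared bottleneck MLP
(C → C/r → C, reduction rate r = 2, ReLU on both layers as in the reference
layer table even though canonical CBAM omits the second), sums and applies a
sigmoid.  The reference equations print both MLP weights as C/r × C; dimensional
consistency requires one transposed, and we implement the standard
bottleneck.  Spatial attention pools over channels (mean and max),
concatenates to an H × W × 2 descriptor and convolves with a 2×1 then a 1×2
single-filter kernel — the reference description names both kernels while
its layer table shows one convolution; stacking them sequentially (an
effective 2×2 receptive field) honours the description.  All convolutions are size-preserving;
even kernels use left-biased padding.

## Numerical and engineering choices

* **No deep-learning framework exists in the target environment**, so the
  package implements the network on BLAS matrix products: narrow kernels
  make convolution a sum over a handful of taps, gathered into a single
  GEMM; electrode-axis kernels exploit the adjacency of the electrode and
  channel axes in the `N x T x E x C` layout to become one structured GEMM
  with no padding or scatter.  Every hand-derived backward pass is verified
  against central finite differences in the test suite (worst relative error
  below 1e-4, with parameters jittered off ReLU kinks where the subgradient
  convention would otherwise disagree with the two-sided difference).
* Batch normalisation uses batch statistics in training and exponentially
  smoothed running statistics (momentum 0.1) at inference; epsilon 1e-5.
* Weights are Glorot-initialised from a caller-supplied seed; identical
  seeds give bit-identical models, and the training loop (shuffling,
  dropout) is seeded the same way, so runs are exactly reproducible.
* Adam (lr 0.001), categorical cross-entropy, and best-validation-accuracy
  checkpointing follow the reference training setup; batch size is unstated
  there and defaults to 128 here.
* Gesture class IDs are remapped to a contiguous internal coding; rest
  (label 0) is never a class.

## The synthetic generator: what it does and does not establish

sEMG is well modelled at second order as amplitude-modulated band-limited
Gaussian noise, and that is exactly what the generator produces: a 10–500 Hz
noise carrier whose per-channel amplitude during a movement is
`region_gain[region] * w[class, channel] * envelope`, with class-specific
channel weights drawn once from the seed, a smooth ramp/plateau/ramp
envelope, a `noise_sd` rest floor, and a 1e-4 physical scale (the ~100 µV
level of raw sEMG, so the Z-score's rescaling from 1e-4 to order 1 is
exercised).  The protocol structure (6 repetitions, 5 s movement, 3 s rest,
2000 Hz, 12 channels, region-dependent gains) is the stated acquisition
protocol.  The posterior label track is emulated by jittering each run
boundary inward by a uniform 0–10% of the run length.  An optional 50 Hz
injector (off by default, since the real DB2 data arrive already
Hampel-filtered by the provider) exercises the filter stage.

The direct fragment generator (`generate_fragment_dataset()`) bypasses
segmentation and controls class structure with a `separation` knob:
class-conditional channel amplitudes are `1 + separation * u[class,
channel]`.  At `separation = 0` classes are exchangeable and no classifier
can beat chance; at large separation the channel-power patterns are linearly
separable.  The default (2) is a deliberately strong-but-noisy setting; the
learning acceptance experiment uses a large separation (4) per its design.

What a green test establishes: the pipeline's bookkeeping (segments, splits,
folds, label handling), the correctness of every layer's forward and
backward pass, and that the full architecture can be optimised end-to-end to
high held-out accuracy on a task whose discriminative signal (spatial
power patterns) matches what the architecture is built to extract.  What it
does not establish: performance on real sEMG, whose nonstationarity,
electrode-shift, crosstalk and inter-repetition variability the generator
does not model — the reference headline accuracies require the real NinaPro
data and GPU-scale training, which are out of scope here.

## Known limitations

* The engine is CPU-only and sized for reduced-width experiments; the
  full-width configuration forward-passes on CPU but is impractical to train
  at dataset scale.
* `.mat` support covers the NinaPro subset of the Level-5 format (real
  numeric arrays, plain or zlib-compressed); v7.3/HDF5 files are not read.
* The fragment container is an RDS file (bit-exact round trip); no HDF5
  library is available in the target environment.
* Per-exercise NinaPro files number gestures per exercise; the reader
  exposes `exercise_id` and leaves any cross-exercise renumbering to the
  caller.
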