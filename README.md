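# semgfusion

An end-to-end R pipeline for **intrasubject hand-gesture recognition from
surface electromyography (sEMG)** under the NinaPro acquisition protocol
(12 electrodes, 2000 Hz, six repetitions per gesture, 5 s movement
alternating with 3 s rest).  It is aimed at researchers in myoelectric
control who want a fully inspectable, CPU-only reference implementation of a
multi-stream attention network and its preprocessing chain, testable without
any external data download.

## What it implements

**Preprocessing** — fourth-order Butterworth band-pass (10–500 Hz,
zero-phase), rest-separated action segmentation on the `stimulus` or
`restimulus` label track, per-channel Z-score normalisation
`y = (x − μ)/σ` fit on training repetitions only, and overlapping
sliding-window fragmentation (200 ms windows, 50 ms steps → 400 × 12
fragments; `⌊(L − W)/S⌋ + 1` windows per segment).

**Augmentation** — time warping: one monotone piecewise-linear time map with
fixed endpoints, applied identically to all channels, controlled by the
number of speed changes and the max/min speed ratio; doubles the training
segments.

**Model** — a multi-stream feature-fusion network: the fragment
`h ∈ R^{400×12×1}` is split by muscle region into streams
`h1 ∈ R^{400×8×1}, h2, h3 ∈ R^{400×2×1}`; each stream runs
BConv(8×1, 64) → residual CBAM → BConv(1×8 or 1×2, 128) → residual CBAM,
where BConv is convolution → ReLU → batch-norm and the residual attention
block is `F' = F + Ms(Mc(F)⊙F) ⊙ (Mc(F)⊙F)` with channel attention
`Mc = σ(MLP(avgpool F) + MLP(maxpool F))` (shared bottleneck C → C/r → C)
and spatial attention `Ms = σ(f^{1×2}(f^{2×1}([avg; max])))`.  Stream
outputs are concatenated along the electrode axis (`H_late`, 128 channels),
fused channel-wise with a 1×1-conv expansion of the raw fragment
(`H_early`, 32 channels) into `H_final` (160 channels), globally
average-pooled, and classified by FC(512) → dropout(0.5) → softmax.

**Training/evaluation** — Adam (lr 0.001), categorical cross-entropy,
best-validation-accuracy checkpointing, the repetition split
{1,3,4,6}/{2,5}, 4-fold repeated-gesture cross-validation,
`Acc = correct/total` per subject and `OA = mean(Acc)` across subjects.

**Synthetic data** — a generator that emulates the acquisition protocol
(label tracks, region-dependent channel activation, band-limited noise
carrier, posterior-label jitter), so every stage is testable in-repo.

The network engine (convolution, batch-norm, attention, Adam) is written in
base R on BLAS matrix products — no deep-learning framework is required —
and every backward pass is verified against finite differences in the test
suite.

## Worked example

```r
library(semgfusion)

# a synthetic 3-class recording under the acquisition protocol
rec <- generate_recording(protocol_config(n_classes = 3, seed = 1))
rec
#> <semg_recording> subject 1, exercise 1: 294000 samples x 12 electrodes @ 2000 Hz
#>   label track 'stimulus': 18 movement runs, 3 gesture classes

prep <- preprocess_recording(rec, augment = warp_config(seed = 2))
str(prep$report)
#> List of 5
#>  $ n_segments       : int 18
#>  $ n_train_segments : int 24        # 12 training segments, doubled by warping
#>  $ n_train_fragments: int 2328
#>  $ n_test_fragments : int 582
#>  $ n_skipped        : int 0

split <- split_by_repetition(prep$train)
split$test <- prep$test
split <- make_folds(split, k = 4)

fit <- train(build_model(model_config_reduced(3), seed = 1),
             split$train[split$folds[[1]]$train_idx],
             split$train[split$folds[[1]]$val_idx],
             train_config(epochs = 3, batch_size = 64, seed = 1))
evaluate(fit, split$test)
#> <eval_result> OA 0.935 over 1 subject(s), 582 test fragments
```

The fragment counts follow directly from the protocol: each 5 s movement at
2000 Hz is 10 000 samples, giving ⌊(10000 − 400)/100⌋ + 1 = 97 windows per
segment; 3 classes × 4 training repetitions × 97 × 2 (warping) = 2328.
`run_demo(seed = 1)` chains the same steps through 4-fold cross-validation
and returns the per-fold OA table.

On the harder synthetic benchmark (8 classes, 200 fragments each, large
class separation), the reduced-width network reaches > 90% held-out
accuracy within 8 epochs on one CPU; with the separation knob at 0 the
classes are exchangeable and accuracy stays at the 1/8 chance level — both
runs are part of the acceptance tests.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the structural targets of the default architecture from scratch:
it generates a synthetic fragment, instantiates the default-width model,
runs one forward pass, and reports the measured channel counts of the
early-fusion, late-fusion and concatenated fusion tensors as JSON.

## Command-line interface

A thin Rscript CLI wraps the package functions:

```sh
inst/cli/semgfusion simulate --classes 3 --seed 1 --out rec.mat
inst/cli/semgfusion preprocess --input rec.mat --label-track restimulus --out prep/
inst/cli/semgfusion train --frags prep/ --fold 1 --epochs 20
inst/cli/semgfusion demo --seed 1
```

See `vignettes/semg-gesture-pipeline.Rmd` for the model, its assumptions,
parameter choices, and what the synthetic experiments do and do not
establish.
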