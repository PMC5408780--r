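---
title: "Models and methods behind locnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind locnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(locnet)
```

This vignette is the package's own account of its science: the classifier
and its training protocol, the screen statistics, the synthetic world the
tests run in, and the places where the design was genuinely open and a
choice had to be made.

## 1. The classification model

`locnet` classifies single cells from fixed-size bounding-box crops rather
than segmented cell masks. A crop is a 64×64 window centered on a cell's
`(x, y)` coordinate (0-based; `x` = column, `y` = row), containing the
GFP channel and one or more marker channels. Working on bounding boxes
removes the sensitivity of downstream analysis to segmentation quality;
the price is that neighboring cells intrude into the crop, which the
network must learn to ignore.

The default architecture (`model_config()`) is eight 3×3, stride-1,
same-padding convolutional blocks with widths 64, 64, 128, 128, 256, 256,
256, 256; each block applies convolution, a bias, batch normalization, and
ReLU, in that order. 2×2/stride-2 max pooling follows blocks 2, 4, and 8.
The 60×60 training input therefore traces 60 → 30 → 15 → 8 spatially
(pooling is ceil-mode — the only convention under which the stated widths,
input size, and the >10-million-parameter total are simultaneously
consistent), flattening to 256·8·8 = 16,384 features, followed by fully
connected layers of 512, 512, and `n_classes` units and a softmax.

Assumptions worth stating:

* **Rotation/reflection invariance of the label.** Localization patterns
  have no preferred orientation, which is why dihedral augmentation is
  label-preserving.
* **Batch norm before every hidden ReLU, none after the final layer** —
  the softmax consumes the raw final affine outputs.
* **Truncated-normal initialization**, σ = 0.1, truncated at ±2σ (the
  common definition; the source protocol states only σ). Batch-norm scale
  and offset start at 1 and 0.
* **Output width is configurable** (default 19): the historical training
  corpus had 17 annotation classes (15 compartments + 2 quality-control
  classes) while the realized network reported 19 output units; the
  discrepancy is not resolvable, so it is exposed as configuration rather
  than guessed away.

### Numerical realization

No deep-learning framework is assumed: convolutions are direct 3×3 C++
kernels over channel-last `(H, W, N, C)` arrays, batch norm and ReLU are
fused C++ passes, and the fully connected algebra uses BLAS. The backward
pass is hand-derived and verified against central finite differences on a
small network in the test suite (`test-network.R`). The input gradient of
a convolution is computed as a convolution with spatially flipped,
channel-transposed kernels.

## 2. Training protocol

`train_config()` defaults encode the full-scale protocol: Adam (β₁ = 0.9,
β₂ = 0.999, ε = 1e-8), base learning rate 0.1 with a *staircase*
exponential decay of 0.96 applied every 25 iterations
(`lr_schedule()` = 0.1·0.96^⌊i/25⌋; "applied every 25 iterations"
describes a discrete application, hence staircase rather than continuous),
batch size 128, 10,000 iterations. Batches are drawn uniformly over the
training set (the historical training corpus was class-balanced by
construction, 185–1,500 cells per class, so no reweighting is applied).
Each batch crop is augmented: a random 60×60 patch (uniform over the 5×5
valid offsets), two independent fair reflection coins, and a uniform
quarter-turn rotation. Every 500 iterations the model is checkpointed and
its validation accuracy recorded; training returns the checkpoint with the
highest validation accuracy (earliest on ties). "Validation performance"
is not further specified in the source protocol; overall accuracy on the
center 60×60 patch is used as the selection metric — the simplest
defensible reading, and cheap enough to run at every checkpoint.

At evaluation time, per-cell predictions are the arithmetic mean of the
softmax outputs over five deterministic patches: center (offset (2,2))
plus the four corners, in the documented order center, top-left,
top-right, bottom-left, bottom-right (`eval_crops()`).

### Transfer learning

`transfer_network()` initializes a new network whose final layer matches
the new class vocabulary, loads pretrained parameters for every other
layer, and fine-tunes *all* parameters (full updating was reported best in
the source protocol) with Adam at a constant 0.003 for at least 500
iterations, dropout 0.5 on the final-layer input (the dropout rate is
unstated in the protocol; the cited dropout paper's default is used, and
it is configurable). For each training-set size, five independent subsets
are drawn per class — without replacement when enough unique cells exist,
with replacement otherwise (`sample_per_class()`) — and per-resampling
held-out accuracies are reported. Passing `pretrained = NULL` spends the
identical budget from random initialization, giving the matched
from-scratch arm. `feature_classifier_baselines()` freezes the network,
extracts the last hidden fully connected activations, and fits
1-nearest-neighbor, a ridge-penalized multinomial linear model, and a
small bagged-tree forest (no SVM or random-forest package is available in
the target environment; these are the closest faithful substitutes).

## 3. Screen statistics

For two conditions A and B and every (protein, class) pair,
`welch_t(a, b)` computes

> t = (mean(b) − mean(a)) / sqrt(s²_a/n_a + s²_b/n_b)

over the per-cell class probabilities, with unbiased sample variances;
positive scores mean the class gained probability under condition B. The
screen pipeline requires at least 5 cells per condition (the statistic
itself needs 2; 5 avoids pathological values and is configurable) and
skips pairs whose variances are both zero.

Per class, the protein scores are calibrated with a two-component mixture:
a Gaussian with free mean and variance for the background, and a uniform
over the observed score range (padded by 1% of the range so the density is
proper) for outliers, whose weight is *fixed* at 1% and not re-estimated —
a literal reading of "set to have a prior distribution of 1%". EM updates
only the Gaussian; the log-likelihood trace is checked non-decreasing. A
score is called an outlier when `π·U(x) > (1−π)·N(x|μ,σ²)`, i.e.
responsibility > 0.5 — the exact formalization of "more likely under the
outlier distribution". The Gaussian is initialized at the median and MAD
so that planted outliers cannot inflate the initial background fit.
Because a probability distribution can change while its argmax does not,
`score_screen()` reports both the outlier call and whether the dominant
compartment changed.

Abundance: per protein and condition, `I_g` is the unweighted mean over
cells of the per-cell mean green intensity by area; `∂PL = log2(I_B/I_A)`,
flagged when strictly above two-fold (`|∂PL| > 1`; the boundary value 1 is
deliberately *not* flagged). In the synthetic screens the per-cell value
is measured on the rendered image within the generator's own body mask —
the stand-in for the segmentation areas a real pipeline would use
(segmentation itself is out of scope).

`build_flux_network()` retains proteins with max |t| ≥ 10 and draws, for
each gaining class (t ≥ +10), an edge from the protein's dominant
condition-A compartment to that class, weighted by |t|. How edge endpoints
derive from per-class scores is not stated in the source protocol; the
argmax-source rule is this package's documented interpretation, flagged as
such.

## 4. The synthetic world

The generator exists so that every downstream operator has a testable
ground truth. `simulate_cell()` renders a 64×64 two-channel crop: the red
marker channel fills an anti-aliased elliptical cell body with random
orientation (axes ~ N(49, (0.12·49)²) × N(37, (0.12·37)²) px — the size
statistics of budding yeast at the imaging scale the classifier targets),
and the green channel follows one of nine compartment patterns: cytoplasm,
nucleus, nucleolus, nuclear periphery, cell periphery, punctate (spot
count encodable in the class name, e.g. `punctate_k8`), bud neck, vacuole,
mitochondria. Intensities live in a 16-bit-like range (green amplitude
8000, red 3000, red background 100, green background 10, additive noise
σ = 25 clipped at zero) and are deliberately left un-normalized so the
0.1-percentile saturation path is exercised downstream. All generators are
pure functions of (parameters, seed); the rendered body and pattern masks
ride along as attributes and serve as oracles in the tests.

`simulate_field()` places cells on a jittered grid (touching allowed) and
returns the true rendered centers; `simulate_screen()` builds two-condition
per-protein populations with planted class shifts and green-intensity fold
changes, recording all truth.

What the generator does **not** emulate: optics (no point-spread function,
no depth of field), illumination gradients, autofluorescence, cell-cycle
morphology (no buds on mothers), crowded colony geometry, or the label
noise of human annotation. A green test therefore establishes that the
*machinery* — optimization, calibration, bookkeeping — recovers planted
truth under realistic intensity statistics; it does not certify
performance on real micrographs.

## 5. Scaled-down benchmarks and runtime choices

The full-scale protocol (10,000 iterations on ~22,000 crops, >10M
parameters) is a GPU-scale computation. The test suite instead trains
`scaled_model_config()` — widths 8, 8, 16, 16 with pooling after every
block and one hidden layer of 64 — for 1,500 iterations on 6 synthetic
classes × 200 crops, which reaches ≥90% (in practice 100%) held-out
accuracy in a few minutes on one CPU. Two runtime choices are documented
here once: the benchmark uses batch 64 for training and batch 16 for
transfer fine-tuning (the 20-example transfer pools make larger batches
meaningless); the protocol-stated quantities — learning-rate schedule,
iteration budgets, checkpoint cadence, resampling counts — are kept as
stated. The null-screen calibration property is exercised at 120 proteins
rather than 500 for the same reason, with the same ≤2% bound.

The transfer benchmark mirrors the structure of the original experiment:
the pretrained model has never seen the four target patterns (vacuole,
mitochondria, nucleolus, 3-spot punctate), and the target dataset is
rendered under a *different acquisition condition* — green amplitude 2500
instead of 8000 and noise σ = 60 instead of 25 — just as a real transfer
targets a dataset imaged with different settings. At full SNR the
synthetic patterns are separable enough that 20 examples suffice even from
scratch, which would make the pretrained-vs-scratch comparison vacuous;
at low SNR generalizing from 5 examples per class genuinely requires the
pretrained features.

## 6. Numerical choices and degenerate inputs

* Percentiles use linear-interpolation empirical quantiles (R type 7);
  the saturation convention is per channel and per crop, configurable.
* A constant channel (both saturation quantiles equal) normalizes to all
  zeros with a warning.
* Out-of-bounds crop regions are zero-padded — zeros are exactly the
  post-normalization background, and crop geometry is preserved.
* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 1e-12.
* Batch-norm uses ε = 1e-5 and running-statistic momentum 0.9; evaluation
  mode is batch-independent by construction.
* AP ties: items with equal scores are processed in stable original order;
  the property tests avoid ties entirely.
* EM stops on absolute log-likelihood change < 1e-8 or 200 iterations,
  returning the best fit with a warning if unconverged.
* Activation-maximization defaults (step 1.0 on RMS-normalized gradients,
  blur σ = 1 px every 4 steps, clip of the lowest 10% |x·∇| contributions,
  L2 decay 0.01 in the regularized preset) are stability choices on the
  synthetic models, not protocol facts; all are configurable and recorded
  in the result object. With every regularizer disabled the regularized
  path reproduces the naive path bit-for-bit (asserted in tests).
* Seeds: one global seed expands into per-purpose streams via
  `derive_seed(seed, counter) = (seed·101 + counter) mod (2³¹−1)`.

## 7. Known limitations

* The from-scratch CNN is CPU-bound; full-scale (widths 64–256, 10,000
  iterations) training is out of reach here — the architecture is
  realized and verified (parameter count, shapes, gradients), but its
  headline real-data accuracies are not reproduced.
* The PNG codec is grayscale-only (8/16-bit); multi-channel images should
  use multi-page TIFF.
* The t-SNE implementation is exact O(n²) — fine for hundreds of cells,
  not for tens of thousands.
* `welch_t` assumes approximately continuous per-cell probabilities; with
  very confident classifiers the probabilities saturate near 0/1 and the
  statistic grows large for modest distributional changes — the mixture
  calibration absorbs this, but the raw |t| values should not be compared
  across classifiers of different sharpness.
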