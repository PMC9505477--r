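---
title: "HEA-Net: model, design choices and what the synthetic experiments show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HEA-Net: model, design choices and what the synthetic experiments show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heanet)
```

## The problem and the model

Histopathology segmentation — outlining glands in colon tissue or nuclei in
multi-organ sections — is hard for exactly the reason it is clinically
interesting: diseased tissue often differs only faintly from its
surroundings, so boundaries are blurred and local intensity alone is
ambiguous. HEA-Net is a U-shaped encoder–decoder for binary segmentation
that attacks this with three light-weight mechanisms layered onto a
convolutional backbone:

1. **Efficient Attention Module (EAM)**, applied after each of the four
   encoder stages. It forms a multiplicative gate
   `E = sigmoid(w_C ⊗ w_S) ⊗ x` from two parameter-free weightings:

   * a *channel* weighting derived from the batch-norm scale factors:
     `w_i = |γ_i| / Σ_j |γ_j|`, broadcast per channel and applied as
     `sigmoid(w ⊗ BN(x))`. Channels whose scale factors survive training
     large are taken to carry more information.
   * a *spatial* weighting from a closed-form minimum-energy score: for a
     pixel `t` in a channel with mean `μ` and biased variance `σ²`,
     `e*_t = 4(σ² + λ)/((t − μ)² + 2σ² + 2λ)` and the pixel's importance is
     `1/e*_t` (`λ = 1e-4` by default). Pixels that stand out linearly from
     their channel's population — edges, salient structures — get weight
     above the constant-channel value of `1/2`.

   The gate lies in (0, 1), so the EAM can only attenuate background, never
   amplify; `|E| ≤ |x|` elementwise is an invariant the tests assert.

2. **Dual-channel Shift MLP (DS-MLP)** at the bottleneck. The feature map
   is split into channel halves: the first half is mixed *spatially* by
   shifting its four channel quarters one pixel in four directions (border
   lines keep their values, exactly the slice-assignment semantics of the
   shift-MLP family); the second half is re-weighted *channel-wise* by
   `sigmoid(conv1d_k3(GMP(x))) ⊗ x`, a global-max-pool descriptor mixed
   across neighbouring channels by a kernel-3 one-dimensional convolution.
   The halves are fused by 2-way split attention — a softmax convex
   combination whose logits come from a bottleneck MLP on pooled
   statistics — and a final linear projection restores the full channel
   count, so the block maps `[C, H, W]` to `[C, H, W]`.

3. **Channel-wise cross fusion transformer (CCT)** skip connections and
   **channel-wise cross attention (CCA)** decoder gates, following the
   UCTransNet family the architecture builds on. Each encoder scale is
   patch-embedded to `d` tokens; per layer, each scale queries the
   channel-concatenation of all four scales, with attention computed along
   the channel axis and `N = 4` heads averaged; `L = 4` layers are applied.
   In the decoder, pooled decoder features gate the skip channels through a
   linear layer and sigmoid before concatenation.

Training uses Adam (learning rate `1e-3`), batch size 4, and an equally
weighted sum of pixel binary cross-entropy and soft Dice loss, with online
flip/rotation augmentation.

## Design choices where the design was open

Several details are under-determined by the construction above; the package
pins them as follows.

* **Negative scale factors.** Batch-norm `γ` can go negative during
  training, which would break the "weights sum to one" reading of the
  channel weighting. We normalise `|γ|` rather than `γ`, keeping the
  weights a convex combination; tests assert the sum-to-one property for
  arbitrary sign patterns.
* **The EAM gate parse.** The output is read as
  `sigmoid(w_C ⊗ w_S) ⊗ x` — the sigmoid produces the gate and the gate
  multiplies the input. Pulling the input inside the sigmoid would destroy
  the residual information path, which no attention-gating design does.
  Note `w_C` is itself already sigmoid-valued; the double squashing is kept
  as stated.
* **Variance estimator.** The energy score uses the biased
  (divide-by-`M`) variance, matching its closed-form derivation.
* **DS-MLP output width.** Split attention fuses two half-width branches
  into `C/2` channels while the block contract demands `C` out; a single
  linear channel projection `C/2 → C` is the minimal reconciliation, and
  the fusion MLP is one layer. The split-attention bottleneck MLP uses
  hidden width `max(4, C/8)`.
* **Channel-shift residual.** The printed gating formula is multiplicative
  (`… ⊗ T2`); no additive skip is added around it.
* **CCT bookkeeping.** Queries keep each scale's full channel width while
  the concatenated key/value channels are partitioned across the `N`
  heads; every head then emits a full `[d, C_i]` map, which makes the
  head-mean well defined. Attention logits are standardised (zero mean,
  unit variance) before the channel-axis softmax; layer norm is applied to
  queries/keys/values and before each output MLP. Patch sizes `(8, 4, 2, 1)`
  give all four scales the same token count.
* **CCA wiring.** The decoder gate is the minimal GAP → linear → sigmoid
  chain; richer two-layer variants exist in the literature but nothing in
  the construction demands them.
* **Skip reconstruction.** After the CCT, tokens are broadcast back to the
  skip resolution and *added* to the original skip, so full-resolution
  detail is never lost to the patch embedding.
* **Encoder/decoder backbone.** Double 3×3 conv + BN + ReLU per stage
  (convolutions carry no bias — batch norm immediately follows), 2×2 max
  pooling, bilinear ×2 upsampling, stage widths `base_width · (1, 2, 4, 8)`,
  a single-logit 1×1 head. The "EAM without BN" ablation replaces the
  channel branch with uniform weights `1/C` and leaves the energy branch
  intact, isolating the batch-norm contribution.
* **Metrics.** `dice = 2TP/(2TP+FP+FN)`, `iou = TP/(TP+FP+FN)`; the
  identity `iou = dice/(2 − dice)` is asserted everywhere. Empty-vs-empty
  masks score 1 by convention. Dataset metrics are means of per-image
  values (protocols also exist that pool pixels; per-image is the common
  benchmark choice and is what the evaluator computes).

## The autodiff substrate

The package implements its own reverse-mode tape: every operation records
its inputs and a backward closure, and gradients are accumulated by a
reverse topological sweep. Convolutions are lowered to a single GEMM
against a `[C_in, 9·C_out]` kernel matrix with compiled scatter/gather
kernels (`src/kernels.cpp`) for the nine spatial taps. Feature maps are
stored `[H, W, batch, C]` so per-channel reductions are column operations.
Every primitive's backward pass is verified against central differences in
the test suite, and a whole-network gradient check runs at toy scale.
Numerical conventions: batch norm uses `eps = 1e-5` and momentum 0.1
(training uses batch statistics, inference the running ones); max-pool ties
route gradients to the first window element; the soft Dice loss uses
smoothing `1e-5`; GELU is the exact `x·Φ(x)` form.

## What the synthetic generators emulate

Real gland and nucleus benchmarks cannot be bundled, so seeded generators
stand in for their two regimes:

* **gland style** — 2–6 large deformed ellipses (Fourier-perturbed radii)
  with interior lumens rendered at background intensity, a smooth
  background texture, a deliberately small foreground/background intensity
  gap (0.15 grey levels before blur) and Gaussian-blurred boundaries. This
  reproduces the *low-contrast, blurred-edge* regime the attention gates
  target; a test asserts the rendered gap never exceeds the configured
  contrast.
* **nuclei style** — dozens of small ellipses on an eosin-like background
  with per-nucleus stain jitter. A configured fraction of nuclei is placed
  touching a host nucleus (offset below the sum of the minor radii
  guarantees contact; placement keeps clear of all others), so the
  mask's connected-component count is exactly
  `n_objects − floor(touch_frac · n_objects)` — a property the tests count
  against a flood-fill oracle.

Augmentation applies independent 0.5-probability vertical and horizontal
flips and a uniform rotation in (−30°, 30°) — "random rotation" needs a
range, and ±30° keeps reflect-padding artefacts mild — with reflect fill
for images, zero fill for masks, and mask re-binarisation at 0.5.

What these generators do *not* emulate: real stain variability, instance
boundaries between overlapping nuclei, tissue-scale context, scanner
artefacts. Passing the synthetic experiments therefore demonstrates that
the architecture, gradients, loss and training loop function and that the
model can learn the low-contrast regime — it does not certify benchmark
accuracy on real histopathology, which requires the public datasets and
GPU-scale training.

## Problem sizes of the bundled experiments

All experiments are sized for a single CPU; the sizes below are the
package's reproducible defaults (`scripts/acceptance.R` re-runs them).

* *Overfit capacity*: base width 16, 64×64 inputs, one fixed batch of 4
  gland images, 200 Adam steps; training Dice is expected to exceed 0.95 —
  in practice it passes 0.95 within ~10 steps and ends near 1.
* *End-to-end*: the same tiny width, 80 generated gland images with a
  seeded 80/20 split (64 trained on, 16 held out), 10 epochs; held-out mean
  Dice is expected ≥ 0.80 and ≥ 0.40 above the untrained network. Note the
  untrained network is not at Dice 0: thresholding its near-constant output
  labels everything foreground, which already scores `2f/(1+f)` for
  foreground fraction `f`.
* *Ablation ordering*: base width 8, 32×32 inputs, 32 images, 14 epochs,
  the five variants (baseline / +EAM without BN / +EAM / +DS-MLP / full)
  over 5 seeds. The expectation is directional only: the full model should
  match or beat each single-module variant in a majority of seeds. At this
  deliberately small scale the variants sit close together and the
  comparison is the noisiest of the suite; the run length is the largest
  that keeps the whole suite inside a desk-scale compute budget.

## Known limitations

* Double precision and R-level elementwise work make training roughly two
  orders of magnitude slower than a GPU framework; the package is sized
  for method verification, not benchmark training.
* Only binary segmentation heads are provided.
* Checkpoints are R serialisations, not portable across frameworks.
* The CCT's head bookkeeping and the CCA's single-layer gate are one
  concrete realisation of designs the literature leaves open; both are
  documented above and isolated behind small functions if a different
  realisation is wanted.
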