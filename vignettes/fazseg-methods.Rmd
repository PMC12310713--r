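---
title: "Segmenting the foveal avascular zone with a feature-location attention U-Net"
author: "fazseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the foveal avascular zone with a feature-location attention U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Optical coherence tomography angiography (OCTA) produces en-face maps of
the retinal capillary network. At the center of the fovea lies the foveal
avascular zone (FAZ) — a capillary-free region whose area and contour
change with diabetic retinopathy and myopia, making its automatic
delineation a clinically useful measurement. On an en-face frame the FAZ
appears as a dark, roughly elliptical region surrounded by bright,
branching capillary texture, corrupted by speckle.

`fazseg` implements a supervised segmentation model for this task: an
encoder–decoder convolutional network (a U-Net) whose decoders carry a
per-channel *feature-location attention block* (FLAB), trained with a
weighted Dice + cross-entropy joint loss. A plain U-Net baseline is built
from the same code path (`use_flab = FALSE`) so that the contribution of
the attention blocks and of the joint loss can be isolated in a controlled
ablation.

## The network

The backbone has five encoder stages and four decoder stages.

* Every conv block is `conv 3×3 → batch norm → ReLU`. Each encoder stage
  applies two such blocks; a 2×2 max-pooling (stride 2) sits between
  stages, halving the resolution while the channel count doubles:
  `w, 2w, 4w, 8w, 16w` channels for a base width `w` (64 in the full-size
  model).
* Each decoder stage upsamples bilinearly by 2× (channel-preserving,
  `align_corners = FALSE` semantics), concatenates the matching encoder
  feature map (skip connection), passes the concatenation through a FLAB
  that halves its channel count, and applies two conv blocks down to the
  stage's nominal width. With base width `w` the concatenated widths are
  `24w, 12w, 6w, 3w` (deepest first), halved by the FLAB to
  `12w, 6w, 3w, 1.5w`, then reduced by the conv blocks to `8w, 4w, 2w, w`.
* A 1×1 convolution maps the final `w` channels to two classes
  (background, FAZ) and a per-pixel softmax yields probabilities; the
  predicted mask is the per-pixel argmax.

Input frames must be divisible by 16 (four poolings). Real OCTA frames
(304–480 px) usually are not; the pipeline either bilinearly resizes to
the configured working resolution or reflection-pads up to the next
multiple of 16 and crops predictions back (`resize_policy`).

## The feature-location attention block

For a concatenated feature map with `C` channels, the block treats each
channel `F_i` separately. Both branches start from the same primitive: a
stride-1, same-size sliding-window average pooling and max pooling of
`F_i` (window `pool_kernel`, default 3), stacked as a 2-channel map.

* The **feature-aware branch** applies `1×1 conv (2→r) → ReLU →
  1×1 conv (r→1)`, a tiny bottleneck over the pooled statistics. The
  hidden width `r` is not dictated by the architecture's published
  description; we use `r = 2`, the smallest width for which the ReLU is
  nontrivial.
* The **location-aware branch** applies a single zero-padded `7×7`
  convolution to the same 2-channel stack, summarizing spatial context.

The two maps are added, squashed by a sigmoid into a gate in (0, 1), and
multiplied elementwise with `F_i` — so gating can only attenuate, never
amplify. The `C` gated channels are then projected by a single plain
`3×3` convolution to `C/2` channels (no BN/ReLU there; the following conv
blocks provide both).

Design choices where the published description is silent or ambiguous:

* **Pooling semantics.** "Average and max pooling" applied to one channel
  that *keeps* its `H×W` shape only makes sense as stride-1 windowed
  pooling with same padding; channel-wise pooling over a single channel
  would be the identity. We use edge replication for the pooling pad (a
  zero pad would fabricate dark borders in the pooled statistics) and
  zero padding for all convolutions (the conventional default).
* **Parameter sharing.** The architecture describes `C` identical
  attention modules; we share one parameter set across all channels of a
  block (`share_across_channels = TRUE`), which is the
  parameter-economical reading, with per-channel parameters available as
  a switch.
* **Initialization.** Kaiming-normal weights, zero biases, from a pinned
  seed; the initialization scheme is unstated in the source description
  and is needed for reproducibility.

## The loss

The training objective is `L = w1 · L_Dice + w2 · L_CE` with
`w1 = 0.8, w2 = 0.2`. Cross-entropy is the mean over pixels of
`−[y log p + (1−y) log(1−p)]` with `p` the FAZ-class probability, clamped
at `1e-7` so hard predictions stay finite. The Dice term is the soft
relaxation `1 − (2Σpy + s)/(Σp + Σy + s)` computed per image and averaged
over the batch; the smoothing constant `s = 1` keeps the loss defined
when both prediction and truth are empty. The exact set form (`s = 0`) is
used by the *metrics* module on hard masks, and the two agree there:
`100 − Dice% = 100 · dice_loss(smooth = 0)`.

Reduction conventions (mean over pixels, then over the batch; Dice per
image then averaged) are our choice — they keep the loss scale
independent of crop size and batch size.

## Metrics

All metrics derive from the pixel confusion counts with FAZ as the
positive class: MIoU (mean of the two per-class IoUs), pixel accuracy,
and the Dice coefficient `2TP/(2TP+FP+FN)`, reported as percentages. A
class absent from both masks contributes IoU 1 (Dice 100) rather than
NaN. Dataset-level aggregation defaults to **macro** (mean of per-image
metrics) with **micro** (pooled counts) always reported alongside; the
report labels which convention its headline numbers use, since the two
genuinely differ.

## Training protocol

The default `train_config()` mirrors the published protocol: Adam with
learning rate 0.01, 200 epochs, batch size 8, 480×480 frames, a 7:3
train/test split, and three independent restarts of which the model with
the best test-set Dice is kept. Two caveats are deliberate:

* Model selection uses the *test* set, reproducing the published
  protocol rather than silently fixing its methodology; a three-way split
  can be emulated by evaluating on held-out data afterwards.
* No augmentation and no learning-rate schedule are applied by default,
  because none are part of the stated protocol (optional flips exist
  behind `augment_flips`).

Everything is seeded: restart `r` trains from seed
`seed + 1000·(r−1)`, shuffling uses R's RNG, and the float32 engine is
single-threaded and deterministic, so a run is bit-reproducible.

## The synthetic data generator

No public OCTA data ships with the package; the generator exists so that
every module is exercisable end-to-end offline. It emulates only the
coarse statistical structure of en-face frames:

* **Mask.** A star-convex region around the image center:
  `r(θ) = r0 · e(θ) · (1 + a·s(θ))` where `e(θ)` is an area-preserving
  ellipse profile (axis ratio drawn from `ellipticity_range`), and `s(θ)`
  is a random low-order harmonic perturbation (orders 2–6, normalized)
  scaled by the `boundary_irregularity` amplitude `a`. Star-convexity
  guarantees one 4-connected component containing the center.
* **Image.** Band-pass-filtered white noise (vessel wavelength ≈ 10 px)
  thresholded at `vessel_density` gives bright capillary texture (0.85)
  on a dimmer perifoveal floor (0.35); the FAZ interior is pulled to a
  dark floor (0.08) through a softly blurred mask edge; multiplicative
  log-normal speckle (`speckle_sigma`) is applied last and the result is
  clipped to [0, 1].
* **Presets.** `normal`, `myopic`, `diabetic` encode only the qualitative
  clinical ordering — larger and more irregular FAZ in diseased eyes
  (mean radius fractions 0.10–0.14 / 0.12–0.17 / 0.15–0.22 of the frame,
  irregularity 0.05 / 0.15 / 0.25). These values were chosen once as
  plausible for 3×3–6×6 mm fields of view and are not fitted to any real
  dataset.

What a green test on this data does establish: the architecture learns,
the gradients are right, the pipeline is wired correctly, and the model
separates a dark central region from textured surround at high Dice.
What it does *not* establish: clinical performance. Real OCTA has
projection artifacts, vessel-density gradients, signal dropout and
annotation ambiguity that the generator deliberately does not model, so
synthetic Dice scores say nothing about Tables of results on OCTAGON,
FAZID or OCTA-500.

## Numerical engineering

There is no deep-learning framework in this package's dependency
universe, so the network runs on a purpose-built float32 engine
(RcppArmadillo): convolutions as chunked im2col + BLAS GEMM, the input
gradient computed as a convolution with the flipped kernel, separable
pooling with recorded arg-max indices, and small pointer kernels compiled
for both generic x86-64 and AVX2/AVX-512 targets with runtime dispatch.
Consequences worth knowing:

* The spec-level operations (`pooled_pair()`, `feature_weight()`,
  `location_weight()`, `flab_forward()`, the losses and metrics) have
  double-precision R reference implementations, tested against scalar
  oracles to 1e-6 or better. The float32 network path is cross-checked
  against these references at float tolerance (≈1e-4 relative).
* The sigmoid gate uses a polynomial `exp` approximation with ≈3e-7
  relative error — far below float32 activation noise, and deterministic.
* Finite-difference checks against the analytic backward pass are exact
  on smooth paths (the softmax head agrees to ~1e-5) but inherently noisy
  for deep parameters, where a perturbation flips ReLU/max-pool cases;
  tests therefore use loose bounds there and tight bounds on smooth ones.
* Batch norm follows running-statistics semantics (momentum 0.1); batch
  size 1 inference is fine in eval mode.

## Scaled-down validation targets

Desk-scale substitutes stand in for full training runs: a base-width-16
model trained 60 epochs on 32 synthetic 160² pairs reaches ≥85% test
Dice on 8 held-out pairs (about 15 minutes on one CPU), and a single
synthetic image is memorized to joint loss < 0.05 within 200 steps. The
three-variant ablation harness (plain U-Net with CE, attention U-Net with
CE, full model with the joint loss) is exercised at toy scale for shape
and determinism only — orderings among variants on synthetic data are
data-dependent and are not asserted.

## Known limitations

* Single-GPU/CPU only; the engine is deliberately minimal (no
  distributed training, no mixed precision beyond float32, no schedules).
* `num_classes` other than 2 is supported by the head and CE, but the
  Dice term always scores class 1.
* The PNG codec covers 8-bit gray/RGB(A) non-interlaced files only.
* Checkpoints store weights as R doubles round-tripped through float32;
  they are exact for the engine but not portable to other frameworks.
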