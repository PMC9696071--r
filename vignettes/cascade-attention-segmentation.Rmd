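---
title: "Cascade attention networks for dental lesion segmentation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade attention networks for dental lesion segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentalseg)
```

## The problem

Intraoral photographs show four common lesion types — dental calculus,
gingivitis, tartar and worn (abraded) enamel surfaces — that an automated
screening system must delineate at pixel level. Two properties make this
hard. First, several lesions (worn surfaces especially) are chromatically
and texturally close to healthy tooth tissue, so local evidence is weak and
models over- or under-segment. Second, screening use demands near-real-time
inference, which rules out heavy encoder–decoder architectures run at full
resolution. `dentalseg` implements a three-branch cascade segmentation
network for this setting, together with the preprocessing, loss, metrics,
synthetic data and training pipeline around it.

## The cascade network

The input image (side `base_size`, divisible by 32) is processed at three
scales:

* **Medium-resolution branch** — the half-scale image passes through a
  residual trunk: a 7×7 stride-2 stem convolution with 3×3 stride-2 max
  pooling, then five bottleneck units (1×1 → 3×3 → 1×1 with identity or
  projected skip). Output stride 8 relative to the full image, `8 × width`
  channels.
* **Low-resolution branch** — continues from the shared trunk features
  (the stem computation is shared with the medium branch, as in the original
  cascade design; `share_stem = FALSE` gives it an independent trunk on the
  quarter-scale input) through a 2× downsample and six further bottleneck
  units whose 3×3 convolutions use dilation 2 at stride 1. Output stride 16,
  `16 × width` channels. Eleven bottleneck-style blocks in total feed this
  branch.
* **High-resolution branch** — three lightweight blocks on the full image,
  each a stride-2 3×3 convolution, ReLU, batch normalization, 1×1
  convolution and ReLU. Output stride 8, `width` channels.

**Cascade feature fusion (CFF)** merges the branches pairwise. The coarser
map F1 is bilinearly upsampled 2×, refined by a 3×3 dilation-2 convolution
and batch-normalized; the finer map F2 is projected by a 1×1 convolution and
batch-normalized; their sum passes through ReLU. A 1×1 auxiliary classifier
on the processed F1 path provides label guidance for deep supervision. The
first fusion combines the low- and medium-branch features (a strict 2× size
ratio); the second combines that result with the high branch. Because both
sit at stride 8 in this topology, the fusion module accepts a size ratio of
1 or 2 and only upsamples when the ratio is 2 — a deliberate design
resolution, since the printed stride pattern (1/16, 1/8, 1/8, classifier at
1/4) cannot be met with strict 2× ratios throughout. The fused map is
upsampled 2×, passed through 2-D dropout (rate 0.1) and a final 1×1
classifier, giving logits at quarter resolution; inference upsamples
bilinearly to full resolution and takes the per-pixel argmax.

**Training loss.** Each branch's logits are scored by softmax cross-entropy
against the label nearest-neighbor-downsampled to the logit resolution, and
combined as

L = W1·L1 + W2·L2 + W3·L3,  (W1, W2, W3) = (1, 0.4, 0.16),

with W1 on the final (high-resolution-path) logits and W2, W3 on the second
and first fusion's auxiliary logits. The weights are exposed via
`cascade_weights()`.

## Attention

A convolutional block attention module (CBAM) gates features sequentially:

* **Channel attention**: `Mc = σ(MLP(avgpool F) + MLP(maxpool F))`, a shared
  two-layer MLP `C → C/r → C` (ReLU between, no biases) on the global
  average- and max-pooled channel descriptors. The reduction ratio `r`
  defaults to 16 (floored at hidden width 1 for thin layers).
* **Spatial attention**: the channel-wise mean and max maps are concatenated
  (2 channels) and convolved to a single channel, then passed through a
  sigmoid. Three convolution variants are implemented: the original single
  7×7 kernel; a single 3×3 kernel with dilation 2; and the improved design,
  two stacked 3×3 dilation-2 convolutions (2→2 then 2→1 channels).

CBAM modules attach *outside* (after the residual addition of) the last
three bottleneck units of the low-resolution branch and the last two of the
medium-resolution branch — five sites. With no biases, the spatial stacks
hold 98, 18 and 54 weights respectively, so replacing the single dilated
3×3 by the stacked pair adds (54 − 18) × 5 = 180 parameters across the
network, and the 7×7 arm adds (98 − 18) × 5 = 400. The bias-free convention
and the 2→2/2→1 stacking were chosen precisely because they make this
delta arithmetic exact and auditable (`attention_ablation_report()`).

A note on receptive fields: by the standard stacked-convolution formula
RF = 1 + Σ d·(k−1), a single 3×3 dilation-2 kernel covers 5 pixels and the
stacked pair covers 9 — neither equals the 7 of a 7×7 kernel, although the
stacked pair brackets it. `receptive_field()` reports the formula value
as-is rather than forcing agreement with any informal equivalence claim.

## Asymmetric convolution

In the designated bottleneck units (the same units that carry attention),
the 3×3 convolution is factorized into a 3×1 convolution followed by a 1×3
convolution with no nonlinearity in between, reducing per-channel-pair
weights from k² = 9 to 2k = 6. The factorized stack reproduces any rank-1
(separable) 3×3 kernel exactly; for general kernels it is a constrained
reparameterization that trades a little expressiveness for compute. Tests
verify the separable-kernel equivalence to 1e−5.

## ACE preprocessing

Overexposed photographs (right-shifted histograms) are corrected by
automatic color equalization. For each channel,

Rc(p) = Σ_{j ≠ p} r(I(p) − I(j)) / d(p, j),

where d is the Euclidean pixel distance and r is an odd, bounded slope
function; we use r(x) = clip(x/T, −1, 1) with threshold `T = 20` by default
(near-linear response for small local contrasts, saturating for large ones).
A second step linearly rescales Rc per channel onto [0, 255], with a
constant-Rc fallback to mid-gray 127.5; rounding (half-up) to 8-bit happens
only at the very end. Because the first step uses only pairwise differences,
the output is *exactly* invariant to a global additive brightness offset —
a property the tests assert bitwise. The pair subset is all pixels for
images up to 64×64 and a square window of radius 31 otherwise (an O(N·|W|)
cost control); both are configurable via `ace_params()`.

## Synthetic scenes

No public dataset of annotated intraoral lesion photographs exists, so the
package ships a seeded generator (`generate_scene()`, `make_dataset()`)
that emulates the *statistical* structure of such a collection:

* bright tooth-like ellipses along a shallow arc over a darker reddish oral
  background, both textured with band-limited noise;
* four lesion classes painted as irregular radius-modulated blobs: calculus
  (yellow-brown, tooth margins), gingivitis (reddened bands at the
  gum–tooth boundary), tartar (high-contrast textured deposits) and worn
  surfaces (low-contrast highlights deliberately close to healthy tooth
  color — the hardest class);
* per-scene lesion counts are Poisson with means 209/200, 215/200, 33/200
  and 100/200, the occurrence pattern of a 200-image clinical collection,
  so tartar appears in roughly 15% of scenes; every scene contains at least
  one lesion (collected lesion photographs do);
* lesion blob radii are 8–14% of the image side so that lesions occupy a
  few percent of pixels — large enough that segmentation metrics are
  non-degenerate, in line with photographs taken *because* lesions were
  visible;
* optional overexposure (gain 1.8 then clipping) and additive Gaussian
  sensor noise (σ = 5).

Every operation is a pure function of `(seed, spec)`. Augmentation
(`augment()`) applies a random crop of side fraction 0.6–1.0 restored to
the original size, a horizontal flip with probability 0.5 and ±20%
brightness/contrast/saturation jitter; ±20% is our choice of magnitude.
Masks use nearest-neighbor resampling throughout, so class ids are
preserved. Datasets are split 7:2:1 into train/val/test, and
tartar-containing scenes can be replicated in the training manifest
(`oversample_rare`) to counter the rarity of that class.

What the generator does **not** emulate: photometric realism, specular
reflections, camera optics, tooth anatomy or 3-D geometry. Passing tests on
synthetic scenes therefore demonstrate that the architecture, loss, metrics
and pipeline are implemented correctly and can fit structured multi-class
scenes — not that any particular clinical accuracy would be reached;
synthetic-data metric values are not comparable to results on clinical
photographs.

## Masks on disk

VOC-style indexed PNGs decode to per-pixel class indices. The `png` package
cannot write palette chunks, so masks are stored as 8-bit grayscale PNGs
whose pixel values *are* the class indices — an exact round trip — and
`voc_palette()` / `colorize_mask()` provide the standard VOC colors (black,
maroon, green, olive, navy for ids 0–4) for rendering overlays.

## Training procedure and numerics

* **Optimizer**: SGD with momentum 0.9, weight decay 1e−4 (not applied to
  normalization affine parameters), initial learning rate 0.01 and
  polynomial decay `lr·(1 − step/total)^0.9`.
* **Early stopping**: training halts once the validation loss has not
  improved for `patience` epochs (default 20) and the best-on-validation
  state is restored; an epoch-level learning-rate drop could be substituted,
  but early stopping is the implemented reading of "stop when validation
  stalls".
* **Rare-class warm-up**: optionally, a few optimizer steps on
  tartar-containing scenes initialize the weights before the main loop.
* **Batch normalization**: batch statistics during training, running
  statistics (momentum 0.1) at evaluation; after each training phase one
  full forward pass re-estimates the running statistics (momentum 1), so
  short desk-scale runs evaluate with statistics that match what was
  trained.
* **Initialization**: He-normal for convolution and MLP weights, unit/zero
  for normalization; all initialization and shuffling derive from explicit
  seeds, so runs are bit-reproducible on a fixed BLAS.
* **Ties and degenerate cases**: argmax ties resolve to the lowest class
  id; mIoU and macro-F1 exclude classes absent from both prediction and
  reference (0/0 unions); background is a class (k+1 = 5) and participates
  in all metrics; overall pixel accuracy is reported, with mean per-class
  accuracy available as `mean_class_acc()`.
* **Engine**: the network runs on the package's own reverse-mode
  autodifferentiation tape with Rcpp kernels for im2col/col2im convolution,
  bilinear resampling (align-corners-false convention) and max pooling.
  Every operation's gradient is validated against central finite
  differences in the test suite.

## Scale of the shipped experiments

The reference residual design corresponds to `width = 64` at 512×512 input.
The test suite and the acceptance script exercise the identical code paths
at `width = 8`, `fuse_channels = 16` and 64×64 scenes with 8–20 images and
up to 300 optimizer steps — sizes chosen so the full suite replays in a few
minutes on one CPU core while still forcing genuinely multi-class fits. The
capability benchmark (overfitting 8 scenes to ≥95% training pixel accuracy
in 300 steps) and the end-to-end pipeline check (generate → train →
evaluate at brightness 0.7/1.0/1.3 → predict) both run at this scale.

## Known limitations

* The engine is CPU-only and tuned for clarity and testability, not
  throughput; wall-clock real-time claims are out of scope.
* Pretrained backbone weights are not available, so transfer learning is
  not offered; training always starts from seeded random initialization.
* The block reading of the residual trunk ("first 11 / first 5 blocks")
  is one defensible mapping (stem + conv2×3 + conv3×2 shared; conv4×6
  dilated for the low branch); other published cascade variants shift
  these boundaries.
* Brightness-robustness evaluation scales intensities linearly; it does not
  model nonlinear camera response.
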