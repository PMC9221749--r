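---
title: "Tiled training for multi-label segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiled training for multi-label segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Panoramic dental radiographs are wide (roughly 2:1) and large, while a
CNN consumes a fixed, much smaller input. Downscaling the whole image to
that input destroys small structures: a root-canal filling a few pixels
wide can vanish entirely, while large compact structures (crowns,
implants) survive. The hypothesis under study is that training on
equally spaced rectangular crops (*tiles*) — which preserves native
resolution at the cost of spatial context — improves pixelwise
multi-label segmentation, most of all for the small, infrequent
root-canal class.

The original study demonstrated this on 1781 clinical panoramics that
are not publicly available. This package therefore rebuilds the entire
protocol around a *synthetic* scene generator whose class geometry
mimics the relevant structure of that data, and asks the directional
question: does the tiling effect reproduce on scenes engineered to have
the same small-versus-large, rare-versus-common class structure?

## The synthetic world

`generate_image()` renders a stylized panoramic: two dental arches of
elliptical teeth on a dark background with a brighter jaw-bone band.
Per tooth, four restoration classes are drawn independently:

| class | geometry | default p/tooth | default area (256x512 canvas) |
|---|---|---|---|
| filling | compact blob in the crown half | 0.45 | 100–260 px |
| crown | cap over the occlusal half | 0.25 | 300–700 px |
| root_canal | thin tapered cone on the root axis | 0.15 | 30–90 px |
| implant | threaded rectangle replacing the tooth | 0.05 | 250–550 px |

All restorations render bright (radiopaque). The root-canal cone starts
past the tooth centre on the occlusal side, so it overlaps a crown cap
whenever both are present; implant screws likewise reach past the
centre (implants carry crowns), so crown+implant pixels overlap too.
An implant suppresses the filling and root-canal draws for its tooth
(a replaced tooth has neither). Masks are therefore genuinely
multi-label, as in clinical annotations where overlapping annotations
share pixels.
Intensity noise and blur are applied to the image only; masks record
exact pre-noise geometry, mirroring expert annotations drawn on clean
structures. Default per-tooth probabilities are order-preserving choices
(no per-class prevalence statistics exist for the clinical data): they
encode only the qualitative ordering *fillings common, crowns moderate,
root canals small and less frequent, implants rare*.

What a green directional test establishes: that the pipeline detects the
resolution-loss effect on scenes with this size/frequency structure. What
it does not establish: anything about absolute clinical performance,
anatomical realism, or the exact magnitudes of the original study
(private data; its F1 of 0.70 at one tile versus 0.95 at twenty is out of
reach by design).

Seeding: image *i* of a dataset uses `mix_seed(seed, i)`, a Lehmer-style
congruential mix modulo 2^31 − 1. Datasets are therefore extensible —
generating 100 images reproduces the first 90 of a 90-image dataset
bit-for-bit.

## Tiling

`select_grid(n, H, W)` picks among all factor pairs `rows x cols = n`
the one minimizing `|log((W/cols)/(H/rows))|` (most-square tiles), ties
broken toward more columns because panoramics are wider than tall.
Boundaries follow `floor(i * extent / k)`: regions partition the image
exactly, per-axis tile sizes differ by at most one pixel, and
`stitch_tiles(extract_tiles(x, r), r, H, W)` is bit-exact for any input.
Tiles never overlap: overlap would require a blending rule the protocol
never defines, and exact partition keeps pixel bookkeeping loss-free.
Coordinates are 0-based, half-open, row-major.

## Model

A compact U-Net-style encoder–decoder (`build_model()`): per encoder
level one 3x3 convolution (instance norm + leaky ReLU) and 2x2 max pooling,
widths doubling from `base_width`; a single bottleneck convolution kept
at the deepest encoder width; per decoder level nearest-neighbour 2x
upsampling, concatenation with the skip, a 1x1 channel-reduction
convolution, and a 3x3 convolution; a 1x1 head with per-channel
logistic output. Channels are independent probabilities — multi-label,
never softmax, because a pixel can carry several annotations at once.

Three choices deserve justification:

* **No pretrained backbone.** The original network was an
  ImageNet-pretrained ResNeXt-50 (32x4d). Pretrained weights are not the
  contribution under study, are not available offline, and the tiling
  effect is architecture-agnostic; the package trains from scratch.
* **Instance normalization, leaky ReLU, and a −2 head bias.** The
  reference backbone carries BatchNorm; a compact net without any
  normalization reproducibly fell into the saturation traps of the Dice
  loss: the sparse root-canal channel saturated at probability 1
  everywhere (for a moderately prevalent sparse class, flooding a
  constant prediction is locally uphill for pooled Dice — the
  derivative of `(2pT+eps)/(pN+T+eps)` in a constant `p` is positive
  whenever `2T² > N`), the rare implant channel at 0 everywhere, and a
  saturated sigmoid passes no gradient, freezing the channel for good.
  Instance norm (per-channel, per-sample standardization with a learned
  affine, identical at train and test time) after every non-head
  convolution keeps logits bounded and removes the trap; the leaky ReLU
  (slope 0.1) avoids dead units; the −2 head bias starts predictions
  near the background prior (sigmoid(−2) ≈ 0.12). All three are
  standard practice for imbalanced dense prediction.
* **Slim decoder.** One 3x3 convolution per level plus a 1x1 reduction
  after each concatenation, and an un-doubled bottleneck. This bounds
  CPU cost; the network still resolves 3-pixel structures at native tile
  resolution, which is all the study requires.

Preprocessing: intensities are scaled to [0, 1] and standardized by
mean/sd computed on the *training* tiles only (stored in the model).
Images and probability maps are resized bilinearly (half-pixel centres,
clamped edges); masks use nearest-neighbour so they stay binary.
Inference on a tile resizes it to the square model input and the
4-channel probability map back to the tile's native size; a tile already
at input size is passed through untouched.

All convolution kernels are hand-written single-threaded C++ (float32
internally, double at the interface). BLAS is deliberately avoided in
the hot path: the environment's OpenBLAS spawns threads that contend on
a single-CPU host and its thread count cannot be controlled from package
code, whereas fixed-order scalar/SIMD loops are fast and
bit-reproducible.

## Training

Soft Dice loss with smoothing `eps = 1`:
`dice_c = (2 Σ p t + eps) / (Σ p + Σ t + eps)`, loss `1 − mean(dice_c)`.
The channel sums pool over the whole batch by default
(`batch_pooled = TRUE`). The per-(channel, sample) alternative is
exposed but not used for training: on 64x64 tiles where a root-canal
cone occupies a few dozen pixels, per-sample Dice makes the gradient
pulling rare positives up ~10^3 times stronger than the gradient
suppressing background, and the sparse channel degenerates to
"predict everywhere" — observed reproducibly in pilot runs, with both
tile settings ending near F1 ≈ 0.01 for the root-canal channel. Batch
pooling is also how the multi-label mode of common segmentation-loss
libraries computes Dice, which is the most plausible reading of the
original pipeline.

Optimizer: Adam with β1 = 0.9 (the protocol's "momentum"), β2 = 0.999.
The stated learning rates "10 × 10⁻⁴" reduced to "10 × 10⁻⁵" are read
literally: 10⁻³ initially, 10⁻⁴ after reduction. (The plausible
alternative 10⁻⁴/10⁻⁵ is one config field away; at desk scale it leaves
a from-scratch network essentially untrained within the epoch budget.)

Schedule: after each epoch the validation loss (no augmentation, pooled
over the whole validation set) feeds a two-stage plateau rule —
*improvement* means `val < best − 10⁻⁴`; five consecutive
non-improving epochs trigger the single LR reduction; five more trigger
the stop. `plateau_schedule()` replays the rule on scripted sequences so
the exact trigger epochs are testable. Weights from the best-validation
epoch are restored at the end (standard with early stopping; the
protocol is silent). Validation is computed on tiles, the same
distribution as training.

Augmentation (training tiles only, fresh draws each epoch): horizontal
flip p = 0.5; rotation uniform in ±10° (applied every draw — the
protocol names no probability, and the uniform angle includes
near-identity); each photometric transform with p = 0.2 —
brightness/contrast ±20%, Gaussian blur σ ≤ 1.5, unsharp-mask
sharpening, additive Gaussian noise sd ≤ 5 (0–255 scale). Geometric
transforms hit image and mask identically (mask via nearest-neighbour);
photometric ones touch the image only. Tiles are resized to the model
input once and augmented at input resolution — equivalent in effect at
these scales and about twice as cheap as augmenting at native tile size.

## Evaluation

Held-out *full* images are tiled with the same tile count used in
training, tiles are predicted, probability maps stitched back, and the
full-image map binarized at 0.5 (a pixel is set iff p ≥ 0.5; the
threshold is a convention, not part of the protocol). Pixel confusion
counts (TP/FP/FN) are pooled *micro* across test images per channel; the
"overall" row pools over the four channels as well. Metrics:
`f1 = 2tp/(2tp+fp+fn)`, `sensitivity = tp/(tp+fn)`,
`iou = tp/(tp+fp+fn)`; the degenerate 0/0 case scores 1.0 (perfect
agreement on an empty class; the alternative of excluding such cases
from pooling is noted here for completeness). Specificity is not
reported: in semantic segmentation the negative class is background.
`oracle_model()` — a predictor that looks the true masks up by image id
and region, optionally corrupted by a fixed full-image pattern — is the
reference that tiling bookkeeping cannot change metrics: its stitched
prediction is identical under any tile count, which would not hold for
any predictor that resizes.

## Cross-validation and the experiment

`make_cv_plan()` shuffles ids once (seeded) into 5 contiguous hold-out
groups of ~20%; per repetition the remaining ids split into 3 folds
(fold = validation, rest = training), giving 15 (repetition, fold)
models; `aggregate_ci()` summarizes the 15 test scores as mean ±
t(0.975, n−1)·sd/√n. A *reduced* plan keeps the 5-group partition but
runs only the first repetition (3 models) — used by the desk-scale
acceptance run. Per-entry training seeds derive deterministically from
the master seed, the tile count and the entry index.

Desk-scale defaults (`desk_scale_defaults()`): 90 synthetic 128x256
images, 64x64 input, depth-3 width-8 U-Net, batch 8, at most 25 epochs,
tile counts {1, 4, 8}. At one tile the 128x256 image is squeezed to
64x64 (2x vertical, 4x horizontal loss); at 8 tiles (2x4 grid) each
64x64 tile is native resolution — the desk-scale analogue of
"224x224 input versus a full panoramic".

## Numerical and reproducibility notes

* All randomness flows through explicit seeds (`with_seed` restores the
  caller's RNG state); identical configuration and seeds give
  byte-identical datasets, histories and result CSVs.
* Convolution results are float32-accurate (~10⁻⁶ relative); gradient
  checks against closed-form double references pass at that tolerance.
* PNG I/O is a built-in minimal codec (8-bit grayscale)
  because the environment provides no PNG package; `memCompress()`
  supplies the zlib stream, chunk CRCs come from compiled CRC-32.
* Grid-selection tie-breaks compare `signif(score, 12)` so that exact
  aspect ties (e.g. 2x6 versus 3x4 on a 2:1 image) are not decided by
  floating-point noise.

## Known limitations

* The generator's scenes are statistical stand-ins, not radiographs: no
  anatomy besides teeth, no projection artifacts, no patient variation.
  Absolute metric values say nothing about clinical data.
* The desk-scale network is far smaller than ResNeXt-50; only the
  *direction* of the tiling effect, not its magnitude, transfers.
* With 3 models per tile setting in the reduced plan, confidence
  intervals are wide; the full 15-model plan is available but slow on
  one CPU.
* Training on one tile count and evaluating with another is unsupported
  by design (the protocol always matches them).
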