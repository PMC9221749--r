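# tileseg

Tiled training for multi-label semantic segmentation of panoramic,
radiograph-like images — an end-to-end, CPU-only R implementation of the
question: *does training a segmentation CNN on equally spaced rectangular
crops (tiles) beat training on the downscaled full image?*

## The problem

Panoramic dental radiographs are wide (≈2:1) and much larger than a CNN
input. Downscaling the full image to the network resolution destroys
small structures: a root-canal filling a few pixels wide simply
disappears, while large compact structures (crowns, implants) survive.
Cutting the image into `n` equally spaced tiles, training on the tiles,
and stitching per-tile predictions back together preserves native
resolution. The package measures the effect of the tile count on
pixelwise multi-label segmentation of four overlapping restoration
classes — **filling, crown, root-canal filling, implant** — where a
pixel may belong to several classes at once.

Because the clinical dataset behind the original study is private, the
package ships a seeded synthetic generator of panoramic-like scenes
whose class size/frequency structure mimics the real one (root-canal
fillings: small, thin, infrequent; crowns/implants: large, compact;
fillings: common), and reproduces the tiling effect *directionally* on
those scenes.

## What is inside

| module | what it does |
|---|---|
| `gen_config()`, `generate_image()`, `generate_dataset()`, `class_frequency_report()` | seeded synthetic scenes with exact 4-channel masks, PNG + JSON manifest I/O |
| `select_grid()`, `tile_bounds()`, `extract_tiles()`, `stitch_tiles()` | exact, non-overlapping grid tiling (bit-exact round trip) |
| `model_config()`, `build_model()`, `predict_tiles()` | compact U-Net (instance norm + leaky ReLU, logistic 4-channel head), hand-written C++ kernels, no BLAS/GPU |
| `train_config()`, `dice_loss()`, `augment()`, `fit()`, `plateau_schedule()` | soft-Dice training with Adam, paired augmentation, plateau LR reduction + two-stage early stopping |
| `binarize()`, `confusion_counts()`, `f1_from_counts()` …, `evaluate_model()`, `oracle_model()` | tile–predict–stitch evaluation, micro-pooled pixel F1 / sensitivity / IoU |
| `make_cv_plan()`, `aggregate_ci()`, `run_experiment()` | repeated 3-fold cross-validation over 5 hold-out groups, tile-count sweep, 95% t-CIs, CSV outputs |
| `tileseg_cli()` (+ `inst/exec/tileseg`) | `synth` / `train` / `cv` / `experiment` / `report` subcommands |

The model is trained with the soft Dice loss
`1 − mean_c (2Σpt + ε)/(Σp + Σt + ε)` (channel sums pooled over the
batch), Adam (β₁ = 0.9, initial LR 10⁻³ reduced to 10⁻⁴ after five
non-improving validation epochs, stop after five more), and evaluated on
held-out **full** images: tiles are predicted, stitched, binarized at
0.5, and pixel TP/FP/FN are pooled per channel (micro) with
`f1 = 2tp/(2tp+fp+fn)`, `sensitivity = tp/(tp+fn)`,
`iou = tp/(tp+fp+fn)`.

## Worked example

```r
library(tileseg)

# 90 synthetic 128 x 256 panoramics, exact multi-label masks
ds <- generate_dataset(gen_config(height = 128, width = 256), 90, seed = 1)
class_frequency_report(ds)

# desk-scale experiment: full image (1 tile) vs 8 tiles,
# repetition 1 of the 5-group CV plan, all 3 folds
# (12 epochs ~ 6 min on one CPU; the package default cap is 25)
dd <- desk_scale_defaults()
dd$train$max_epochs <- 12L
res <- run_experiment(ds, tile_counts = c(1, 8),
                      model_cfg = dd$model, train_cfg = dd$train,
                      seed = 1, repetitions = 1, folds = 3)
print(res)
subset(res$summary, metric == "f1" & channel %in% c("overall", "root_canal"))
```

Output of this exact run:

```
> print(class_frequency_report(ds))
     channel object_count mean_object_area pixel_prevalence
1    filling         1046         44.76864      0.015878635
2      crown          608        120.88980      0.024923028
3 root_canal          350         27.73429      0.003291490
4    implant          143        131.59441      0.006380887

> print(res)
experiment_result
 tile_count   mean  ci_low ci_high mean_epochs_to_stop
          1 0.4261 0.02691  0.8253                  12
          8 0.7975 0.60520  0.9899                  12

> subset(res$summary, metric == "f1" & channel %in% c("overall", "root_canal"))
 tile_count    channel metric   mean  ci_low ci_high n mean_epochs_to_stop
          1 root_canal     f1 0.0469 -0.0545   0.148 3                  12
          1    overall     f1 0.4261  0.0269   0.825 3                  12
          8 root_canal     f1 0.6107 -0.0797   1.301 3                  12
          8    overall     f1 0.7975  0.6052   0.990 3                  12
```

Reading the numbers: downscaling the whole 128 x 256 scene into the
64 x 64 input almost erases the thin root-canal cones (F1 0.05 at one
tile); at 8 tiles each 64 x 64 crop is native resolution and the same
class reaches F1 0.61, while overall F1 moves from 0.43 to 0.80 — the
directional tiling effect the package exists to measure. (With only 3
fold models per setting the t-intervals are wide; the full 5 x 3 plan
narrows them at 5x the cost.)

The overall row pools pixel counts over all four channels; the
root-canal row is the small, infrequent class whose gain from tiling is
the study's headline observation. `res$summary` carries mean and 95%
Student-t confidence intervals over the fold models, and
`res$convergence` the per-model stop epochs.

## Command line

```sh
tileseg synth --config cfg.json --n 90 --seed 1 --out data/
tileseg experiment --config cfg.json --data data/ --out results/
tileseg report --results results/
```

`cfg.json` is a declarative JSON file with optional sections `gen`,
`model`, `train` and scalars `tile_counts`, `seed`, `repetitions`,
`folds`, `n_images`; missing fields use package defaults.

## Design notes

See the methods vignette (`vignettes/tiling-methods.Rmd`) for the
synthetic-scene model, the loss/optimizer/schedule choices, what a green
directional test does and does not establish, and known limitations.
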