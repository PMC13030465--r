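# culmseg

Instance segmentation of densely packed plant cells in cross-section images
of bamboo culm tissue, for plant anatomists and phenomics researchers who
need per-cell masks (not just per-pixel classes) from microscopy or micro-CT
slices. Bamboo tissue is a hard case: irregular polygonal parenchyma cells
share thin walls, vascular bundles mix very large vessel lumens with tiny
thick-walled fibers, and images carry local overexposure and noise.

## What the package implements

* **A triple-branch attention U-Net.** Three structurally identical,
  parameter-independent encoder–decoder branches predict a 3-channel
  semantic map (background / parenchyma / vascular bundle), a cell-wall
  (boundary) map and a cell-interior map. After every encoder stage and
  every decoder fusion a cascaded channel–spatial attention block is
  inserted: channel gates `s = σ(W₂ δ(W₁ z))` from the globally pooled
  descriptor `z` (reduction ratio `r`), then a pixel gate
  `P = σ(conv₇ₓ₇([A; M]))` from the channelwise mean/max maps. The block is
  bias-free, so its weight count is exactly `2C²/r + 98`. Forward and
  backward passes are implemented in the package (im2col convolutions in
  compiled code) and checked against finite differences in the tests.
* **The combined objective** `L = λ·L_BCE + (1−λ)·L_Dice` per head (soft
  ε-smoothed Dice on raw probabilities), optimized with RMSprop
  (defaults: learning rate 1e-4, decay 1e-15, batch 12, 150 epochs).
* **Boundary-guided instances.** Probability maps are thresholded
  (inclusive ≥ 0.5), interiors = region ∧ ¬boundary fall apart along
  predicted walls, connected components (4-connectivity by default) become
  instances with per-instance class and confidence; optional wall
  reclamation and size filtering.
* **Evaluation**: Dice `= (2Σyŷ+ε)/(Σy+Σŷ+ε)`, IoU `= Σmin(y,ŷ)/(Σmax(y,ŷ)+ε)`,
  overall accuracy, and mask mAP50–95 (greedy confidence-ordered matching at
  IoU thresholds 0.50–0.95, all-point interpolated PR curves; Hungarian
  matching behind a flag).
* **A synthetic tissue generator** (seeded Voronoi tessellation with exact
  instance/class/wall ground truth, vessel cells, overexposure blobs, noise,
  blur) so the whole pipeline is testable without proprietary data, plus the
  data pipeline: 3×3 patching, 8:2 and 5-fold splits, one-hot encoding, and
  synchronized rotation/flip/brightness/hue augmentation.
* **I/O**: PNG/16-bit TIFF images and label maps, LabelMe-style polygon
  JSON, plain-text contour files, YAML run configs, JSON-lines manifests.

## Worked example

Generate a synthetic tissue image, build idealized predictions from its
ground truth, extract instances and score them:

```r
library(culmseg)

s <- generate_tissue(synth_config(128, 128, n_cells = 40, seed = 5))
s
#> <image_sample> 128 x 128, 40 instances, classes: 0,1,2

pr   <- predictions_from_truth(s, p_hi = 0.95, p_lo = 0.05)
inst <- extract_instances(pr, threshold = 0.5, connectivity = 4)
inst
#> <instance_set> 40 instances on 128 x 128

tg <- derive_targets(s)
gt <- instance_set(s$instance_map * (tg$interior == 1),
                   class_mask = s$class_mask)
pred_class <- apply(pr$semantic, c(1, 2), which.max) - 1L
evaluate_segmentation(pred_class, s$class_mask, inst, gt)
#> Dice 1.0000  IoU 1.0000  OA 1.0000  mAP50-95 1.0000
```

All 40 generated cells are recovered and every metric is 1 because the
predictions were built from the ground truth — this exercises the
discretization, labeling, matching and mAP machinery end to end. Attention
bookkeeping is equally direct:

```r
p <- attention_params(64, 16, rng = rng_new(1))
attention_weight_count(p)
#> $channel 512   $spatial 98   $total 610   $closed_form 610
```

Training runs through `build_model()` / `train_model()`; a reduced model
(depth 3, 16 base channels) overfits four 64×64 synthetic tiles to a
semantic Dice above 0.9 in under 200 RMSprop steps on one CPU — see the
training smoke test in `tests/testthat/test-acceptance.R`.

A command-line surface wrapping the same functions ships at
`inst/cli/culmseg.R` (after install: `system.file("cli", "culmseg.R",
package = "culmseg")`) with the commands
`generate | prepare | train | predict | instances | eval`.

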