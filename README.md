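# cineseg

Contrast-free segmentation of cardiac structures and localization of
myocardial infarction from short-axis cine cardiac MRI — no gadolinium, no
LGE sequence. The package is aimed at researchers building or auditing
cine-CMR analysis pipelines: it implements the full chain as tested,
deterministic R code, and ships a synthetic cine phantom generator so every
stage can be exercised end-to-end without any clinical download.

## What it implements

* **Structure segmentation as mask regression.** Four compact CNNs map a
  64×64 ROI to a flattened 32×32 mask through a dense sigmoid layer:
  *shallow* (100 filters 11×11, 6×6 average pooling), *max-pool*, *larger*
  (200 filters) and *deeper* (64@11×11 → 128@10×10), all with L2
  (λ = 10⁻⁴) on the dense weights, trained with Adam (lr 0.001, batch 16,
  20 epochs, MSE). With valid convolutions and stride-equals-size pooling
  the trainable-parameter counts are exactly 8,307,624 / 8,307,624 /
  16,614,224 / 11,444,992 — reproduced bit-exactly by
  `count_trainable_params()`.
* **Shape refinement.** A three-stage stacked autoencoder (latent width
  100) denoises predicted masks under the hybrid loss
  `L = (α/2)·MAE + β·KL(y‖ŷ)` with α = 10⁻⁴, β = 3, followed by a
  semi-implicit active contour (elasticity 0.01, curvature 0.1) attracted
  to the smoothed image's edge map.
* **Infarct localization.** An attention U-Net with squeeze-and-excitation
  blocks (encoder 32/64, bottleneck 128, gated skips, 128×128×3 in,
  128×128×1 sigmoid out) trained with the composite loss
  `0.5·Dice + 0.5·Focal(α = 0.25, γ = 2)`, Adam 10⁻⁴, early stopping
  (patience 5) and plateau LR halving (patience 3).
* **Evaluation.** Dice, precision/recall/F1/accuracy, mean contour
  distance, Hausdorff distance, ROC-AUC, percentile bootstrap CIs
  (1000 iterations) and Holm–Bonferroni-corrected paired t-tests — each
  validated against brute-force oracles to 1e-9.
* **Hemodynamics.** Aortic distensibility
  `D = (A_max − A_min)/(A_min·CPP) · 10³` with the CPP < 10 mmHg exclusion
  rule.

The neural-network engine (im2col GEMM convolutions, batch norm, SE and
attention backward passes, fused in-place Adam in C++) is part of the
package; every backward pass is finite-difference-tested.

## Worked example

```r
library(cineseg)

# a 20-frame synthetic cine study with ground truth
case <- generate_phantom(phantom_config(seed = 7))
phantom_areas(case)[1:3, ]
#> # A tibble: 3 × 3
#>   frame structure     area_px
#>   <int> <chr>           <dbl>
#> 1     1 lv_cavity        3247
#> 2     1 lv_myocardium    2596
#> 3     1 rv_cavity        2179

# train the shallow CNN on 200 phantom ROIs and evaluate held-out Dice
ds    <- phantom_roi_dataset(120, frames_per_case = 2, seed = 9001)
items <- unlist(lapply(ds$cases, identity), recursive = FALSE)
model <- train_structure_model("shallow", items[1:200],
                               train_config(epochs = 20, seed = 1))
glance(model)
#> # A tibble: 1 × 6
#>   arch    n_params loss  epochs first_loss final_loss
#>   <chr>      <dbl> <chr>  <int>      <dbl>      <dbl>
#> 1 shallow  8307624 mse       20      0.187     0.0174

pred <- binarize(predict_structure_mask(model, items[[201]]$x))
dsc(pred, resample_mask(items[[201]]$y, 32))
#> [1] 0.9863302
```

The Dice of ≈ 0.99 says the mask-regression formulation recovers the
phantom's LV cavity almost perfectly after 20 epochs; the training loss
falling from 0.187 to 0.017 is the monotone convergence the fixed 20-epoch
schedule relies on. On the harder refinement benchmark
(`refinement_ablation()`, 100 corrupted masks), corrupted masks start at
mean Dice 0.776 and Hausdorff 13.0 px, SAE refinement lifts them to
0.980 / 1.20 px, and the snake adds a final boundary polish
(0.984 / 1.10 px) — the same direction-of-improvement the full clinical
pipeline reports.

A thin CLI covers phantom generation and pipeline runs:

```sh
Rscript inst/cli/cineseg phantom --n-cases 5 --seed 1 --out phantoms/
Rscript inst/cli/cineseg run --ablation full --seed 1 --out run1/
```

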