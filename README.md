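# cine2tag

Deep-learning segmentation of the myocardium works well on bright-blood
*cine* cardiac MR images, where large expert-annotated public datasets
(ACDC, M&Ms, SCD) exist — but not on *tagged* images, where annotations
are scarce. `cine2tag` addresses the data gap from the simulation side:
it turns annotated cine short-axis images into **tagged-appearing**
images by simulating the MR physics of a grid-tagging preparation, and
transfers each cine image's myocardium mask untouched to its transformed
counterpart. Because the transformation only modulates intensities, the
anatomy — and therefore the annotation — is preserved, yielding labelled
pseudo-tagged training data for free.

The package is aimed at researchers building or evaluating myocardial
segmentation models for tagged CMR. It provides:

- **Physics-driven cine-to-tagged transformation** (`transform_cine_to_tagged`):
  an element-wise square root approximates the bSSFP-to-gradient-echo
  contrast change; tag lines are added on an equally spaced rotated grid
  by Bloch simulation of a SPAMM preparation with a 1-3-3-1 binomially
  weighted RF pulse train (defaults: 5-px tag spacing, 70° total flip,
  45° grid rotation). For each inter-pulse gradient phase ψ the
  magnetization, starting at M = (0,0,1), is alternately tipped about x
  by wᵢ/Σw·α and precessed about z by ψ; after spoiling, the surviving
  Mz(ψ) modulates the image. Two orthogonal 1D preparations multiply
  into the grid. Optional T1 fading, Mz(t) = 1 + (Mz(0) − 1)·e^(−t/T1),
  is off by default (tag lines are static across frames).
- **Boundary-aware shape loss** (`shape_loss`, `combined_loss`): with
  H(x) = 1/(1 + e^(−x/k)) and φ the signed normalized Euclidean distance
  map, the shape information SI(m) = H(1 − φ(m)) on the foreground (0
  outside) peaks at the mask boundary; the loss is
  L_S = (1/C)·Σ_c (1/Σg_c)·Σ_i |p_ci − SI(g_c)_i|, and the combined
  objective is L = (1 − Dice term) + CE + γ·L_S (defaults k = 0.2,
  γ = 0.05).
- **Evaluation metrics** (`dice_coefficient`, `hausdorff95`,
  `evaluate_masks`): Dice overlap 2|G∩P|/(|G|+|P|) and the symmetric
  95th-percentile Hausdorff distance between mask contours in mm.
- **Deterministic augmentation** (`augment_pair`, `preprocess`): flips,
  noise, blur, affine and elastic deformations, seedable per draw; plus
  256×256 resize and (x − 0.456)/0.224 input normalization.
- **Synthetic phantom** (`phantom_config`, `generate_phantom_series`):
  a contracting annular-myocardium phantom with bSSFP-like contrast
  ordering over a 25-frame cycle, so everything is testable offline.
- **Pipeline + I/O** (`transform_dataset`, `read_slice_pairs`):
  ACDC-style NIfTI (image + `_gt` label companion, myocardium label 2)
  and PNG-pair layouts, CSV manifests, and a CLI.

## Worked example

```r
library(cine2tag)

cfg <- phantom_config(image_size = 128, r_endo_ed = 18, r_epi_ed = 28,
                      n_frames = 25, noise_sd = 0.02, seed = 1)
fr  <- generate_phantom_frame(cfg, 0)
out <- transform_cine_to_tagged(fr$image, fr$mask, 0, tag_config())

measure_tag_period(out$image, rotation_deg = 45)
#> [1] 5
identical(out$mask, fr$mask)
#> [1] TRUE

l <- combined_loss(fr$mask, pmin(pmax(fr$mask + 0.1, 0), 1),
                   loss_config(k = 0.2, gamma = 0.05))
round(unlist(l), 4)
#>        total     dice_term cross_entropy         shape
#>       0.3914        0.6604        0.0000        1.0369
```

The measured period of 5 px confirms the tagging grid reproduces the
configured tag spacing; the mask is bit-identical to the input (the
annotation transfer that makes the simulated data usable for training).
The loss components are the soft Dice term (1 means perfect overlap; its
loss contribution is 1 minus it), the foreground cross-entropy, and the
boundary-aware shape term weighted by γ.

The same workflow runs from the shell via the thin CLI:

```sh
Rscript inst/cli/cine2tag.R phantom   --out cine_dir --n-subjects 2 --frames 25 --seed 1
Rscript inst/cli/cine2tag.R transform --in cine_dir --out tagged_dir --spacing-px 5 --flip-deg 70
Rscript inst/cli/cine2tag.R eval      --pred preds --gt labels --pixel-mm 1.0 --out report.csv
```

## Acceptance script

`scripts/acceptance.R` exercises the full pipeline from scratch —
phantom generation, dataset transformation with mask transfer,
tag-period measurement, metric aggregation and loss evaluation — and
writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
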