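# pxsal — point-supervised multiscale saliency detection for pelvic radiographs

`pxsal` is an R implementation of a weakly supervised detection pipeline for
trauma-related findings on pelvic radiographs (PXRs): hip fractures,
pelvic-area fractures, hip dislocations, periprosthetic fractures and femoral
shaft fractures. It is written for researchers who have per-image **point
annotations** — a mark at the centre of each visible finding — rather than
bounding boxes or segmentations, and who want both an image-level probability
and a localization heatmap, plus the statistical machinery to evaluate them
against readers.

## The method

**Supervision masks from points.** Each annotation point becomes a binary
disk of radius *s* = 75 pixels (at the 1024-pixel working resolution);
overlapping disks take their union. The disk is a noisy but informative
pixel-level target for findings whose true extent is unknown.

**Multiscale saliency network.** An encoder–decoder ("feature pyramid")
network maps one preprocessed 1024×1024 grayscale image to four saliency
logit maps P₁…P₄ of 32², 64², 128² and 256² pixels. Every annotation point
supervises every level: the mask M is max-pool-downsampled to each level size
Ωₖ and the loss is the multiscale pixel-wise binary cross-entropy

    L = Σₖ (1/Ωₖ) Σᵢⱼ −[ Mₖ(i,j) log σ(Pₖ(i,j)) + (1−Mₖ(i,j)) log(1−σ(Pₖ(i,j))) ]

The image-level score is max σ(P) over the designated output map.

**Fivefold CV + bagged test-time augmentation.** Training runs fivefold
cross-validation (Adam, per-epoch validation AUROC, best epoch kept per
fold). At inference the 5 fold models each score 5 augmented copies of the
input (flip / rotation / contrast families), giving N = 25 member maps Pⁿ
and

    p = (1/N) Σₙ maxᵢⱼ σ(Pⁿ(i,j))

Member maps are inverse-transformed, realigned and averaged into a fused
localization map rendered as a red overlay.

**Evaluation battery.** AUROC/AUPRC with 2000-replicate percentile-bootstrap
95% CIs, Youden-J operating cutoff, accuracy/sensitivity/specificity/PPV/NPV,
per-category sensitivity tables, McNemar paired tests (exact below 25
discordant pairs), and a three-class reader-study harness (hip fracture /
pelvic fracture / normal; one-vs-rest tasks, balanced accuracy,
misdiagnoses-detected counts).

Because clinical PXRs are restricted, the package includes a synthetic
phantom generator (pelvis-like ring + femur primitives with five insertable
lesion appearances and exact ground-truth points) so the entire pipeline is
testable end-to-end. See `vignette("point-supervised-detection")` for the
model's assumptions, parameter choices and limitations.

## Worked example

```r
library(pxsal)

# 1. a synthetic cohort: 200 phantoms at 128 px, half with lesions
manifest <- generate_dataset(n = 200, positive_fraction = 0.5,
                             config = phantom_config(image_size = 128),
                             seed = 3, out_dir = "demo")

# 2. point annotations -> multiscale disk supervision masks
pyr <- build_supervision_pyramid(manifest$points[[1]],
                                 mask_config(radius_s = 9.375, mask_size = 128,
                                             level_sizes = c(4, 8, 16, 32)))
pyr
#> <supervision_pyramid> levels: 4, 8, 16, 32 | positives: 2, 4, 9, 26

# 3. fivefold cross-validation at desk scale
cv <- run_cross_validation(
  manifest, model_config("tiny_fpn", input_size = 128, output_level = "finest"),
  train_config(epochs = 20, batch_size = 4, learning_rate = 3e-3, folds = 5,
               seed = 1, input_size = 128))
tidy(cv)
#> # A tibble: 5 × 4
#>    fold best_epoch best_validation_auroc checkpoint
#>   <int>      <int>                 <dbl> <chr>
#> 1     1         18                 1     <NA>
#> 2     2         19                 0.875 <NA>
#> 3     3         20                 1     <NA>
#> 4     4         19                 0.98  <NA>
#> 5     5         16                 1     <NA>

# 4. bagged 25-member TTA ensemble + the evaluation battery
cohort <- predict_manifest(lapply(cv$folds, `[[`, "model"), manifest)
report <- evaluate_cohort(cohort, n_boot = 2000, seed = 1)
report
#> <eval_report> n = 200 (100 positive), cutoff = 0.1705
#> # A tibble: 7 × 4
#>   metric      estimate ci_lower ci_upper
#>   <chr>          <dbl>    <dbl>    <dbl>
#> 1 auroc          1        1        1
#> 2 auprc          1        1        1
#> 3 accuracy       1        1        1
#> 4 sensitivity    1        1        1
#> 5 specificity    1        1        1
#> 6 ppv            1        1        1
#> 7 npv            1        1        1
```

Each fold's `best_validation_auroc` is the maximum per-epoch validation AUROC
(the checkpoint kept for ensembling); the report rows are the cohort metrics
at the Youden-J cutoff with percentile-bootstrap 95% CIs. On this phantom
cohort the trained ensemble separates positives perfectly — phantom lesions
are deliberately conspicuous; see the vignette for what this does and does
not say about clinical data.

## Command-line interface

`inst/cli/pxsal.R` exposes the pipeline as subcommands, each writing its
resolved YAML config and a log next to its outputs:

```sh
Rscript inst/cli/pxsal.R synth    --n 200 --positive-fraction 0.6 --size 256 --seed 1 --out data/
Rscript inst/cli/pxsal.R train    --annotations data/annotations.jsonl --out run/ --seed 1
Rscript inst/cli/pxsal.R predict  --models run/checkpoints --images data/ --out pred/
Rscript inst/cli/pxsal.R evaluate --scores pred/scores.csv --out eval/
Rscript inst/cli/pxsal.R readerstudy --responses study.csv --out reader/
```

`train` writes `checkpoints/fold_1.rds … fold_5.rds` and `history.json`;
`predict` writes `scores.csv` (image_id, score, label, categories), per-image
JSON and overlay PNGs; `evaluate` writes `report.json` / `report.md`;
`readerstudy` writes `reader_report.json` / `reader_report.md`.

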