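---
title: "Point-supervised multiscale detection of trauma findings on pelvic radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-supervised multiscale detection of trauma findings on pelvic radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pxsal)
```

## The problem and the model

Pelvic radiographs (PXRs) are read under time pressure for several concurrent
trauma findings — hip fractures, pelvic-area fractures, hip dislocations,
periprosthetic fractures, femoral shaft fractures. Bounding boxes are hard to
define for these findings; a practical weak-supervision scheme instead marks a
single point at the centre of each visible finding. `pxsal` implements a
detection pipeline built entirely on such point annotations:

1. **Disk supervision masks.** Each annotation point is dilated into a binary
   disk of radius $s$ pixels (default $s = 75$ at the 1024-pixel working
   resolution); overlapping disks take their union. The disk radius encodes
   the irreducible uncertainty about a finding's extent: the mask is a noisy
   but informative pixel-level target.
2. **Multiscale saliency network.** A convolutional encoder produces feature
   taps at strides 4, 8, 16 and 32; a top-down path fuses them
   (1×1 lateral convolutions, nearest-neighbour upsampling, addition) and a
   per-level 1×1 head emits one logit map per level — at the default
   1024-pixel input, maps of 32², 64², 128² and 256² pixels, coarse to fine.
3. **Multiscale pixel-wise BCE.** Every annotation point supervises every
   level: the full-resolution mask is max-pool-downsampled to each level size
   $\Omega_k$ and the loss is
   $$L = \sum_{k=1}^{4} \frac{1}{\Omega_k} \sum_{i,j}
     -\left[M_k \log \sigma(P_k) + (1 - M_k)\log(1 - \sigma(P_k))\right].$$
   The image-level score is the maximum of $\sigma(P)$ over the designated
   output map.
4. **Fivefold cross-validation** with per-epoch validation AUROC; the
   highest-AUROC epoch per fold is kept as that fold's checkpoint.
5. **Bagged test-time-augmentation inference.** The five fold models are each
   applied to five predefined augmented copies of the input (identity,
   horizontal flip, ±10° rotation, contrast 1.15 by default — the families
   are fixed, the magnitudes are configuration), giving $N = 25$ member maps
   $P^n$ and the image probability
   $$p = \frac{1}{N} \sum_{n=1}^{N} \max_{i,j} \sigma\!\left(P^n(i,j)\right).$$
   For localization, each member map is inverse-transformed to realign with
   the input and the aligned maps are averaged into a fused map, rendered as
   a red overlay.
6. **Evaluation battery.** AUROC and AUPRC with percentile-bootstrap 95% CIs
   (2000 case resamples), a Youden-J operating cutoff, confusion metrics,
   per-category sensitivity, McNemar paired comparisons, and a three-class
   reader-study harness (hip fracture / pelvic fracture / normal, scored
   one-vs-rest per fracture task with balanced accuracy over the three
   classes).

## Design choices in ambiguous territory

Several aspects of the published design admit more than one reading; the
package fixes them as follows and exposes each as configuration.

**Output level.** The method is described both as emitting a 32×32
probability heatmap and as producing only the finest (256×256) map at
inference. `pxsal` keeps both: `model_config(output_level = ...)` selects the
map used for the image-level maximum (default `"coarsest"`, the 32×32
heatmap), while the fused localization map is naturally computed at whichever
level the members used. Desk-scale experiments in this package use
`output_level = "finest"`, where the localization peak is meaningful at small
image sizes.

**Loss form.** The second BCE term is implemented as
$\log(1-\sigma(P_k)) = \log \sigma(-P_k)$, the standard form that vanishes
for confidently correct negatives. The loss is evaluated in the stabilized
logit formulation $\max(P,0) - PM + \log(1+e^{-|P|})$, exact to $10^{-10}$
against direct per-pixel arithmetic in the tests.

**Mask downsampling.** The downsampling operator from the 1024² mask to the
pyramid levels is block max-pooling (`mask_downsample = "max"`): a 75-pixel
disk then survives even at the 32× stride, which is what "assigning every
point to all levels" requires. An area-threshold variant
(`"area_threshold"`, block mean ≥ 0.5) is available; it can erase small
disks at coarse levels and is not the default.

**Disk membership.** Distance is measured from annotation point to pixel
centre, inclusive at exactly $s$; points are 0-based with the origin at the
top-left pixel centre, x = column, y = row. Everything in the package uses
this one convention.

**Fold splitting** is stratified by image-level label. A plain random even
split is fine at thousands of images, but desk-scale runs (tens to hundreds)
need both classes in every validation fold for AUROC to exist; a degenerate
fold is an error, not a silent skip.

**Ensemble bookkeeping.** Member maxima are taken on the raw member maps
before inverse transformation, so $p$ is exactly the mean of member maxima
regardless of interpolation. After inverse rotation, unsupported border
pixels are filled with the map's minimum, not zero — in sigmoid space, zero
would fake a maximally confident negative at the borders of the fused map.

**McNemar branches.** With discordant count $b + c < 25$ the exact two-sided
binomial test is used, otherwise chi-square with continuity correction; the
switch point is conventional and configurable. Bootstrap CIs are percentile,
case-resampled, non-stratified by default (a stratified option exists);
single-class resamples are redrawn so the metric is evaluated exactly
`n_boot` times.

**Operating cutoff.** The reference deployment used a review-board-defined
cutoff; absent a review board, the default is the Youden-J maximizer over
midpoints between consecutive distinct scores, ties broken toward higher
specificity, with `score >= cutoff` a positive call. A literal cutoff can be
supplied wherever the Youden default is used.

## The synthetic phantom generator

Clinical PXRs are restricted data, so the package ships a generator of
pelvis-like phantoms: a bright annulus (pelvic ring), two femoral-head disks
and two capsule shafts on a dark background, Gaussian-blurred, with additive
Gaussian noise and per-image geometry jitter. Five lesion appearances mirror
the clinical category vocabulary: `fracture_line` (jagged dark polyline),
`fracture_gap` (wider dark band), `dislocation` (offset bright head plus dark
vacancy), `periprosthetic` (bright implant stem with adjacent dark line),
`shaft_fracture` (dark line on the shaft). Every rendered lesion is centred
at its annotation anchor and confined to a disk of radius `0.07 * image_size`
around it, comfortably inside the supervision-mask radius at the matching
scale — so the annotation point provably sits inside the lesion's support.

Defaults are chosen to emulate the study conditions at desk scale: 256-pixel
images by default (128 in the training experiments; 1024 supported), a
configurable positive fraction (the development cohort was ~60% positive,
the clinical test cohort ~33%), 1–7 annotation points per positive image
with median 1, and lesion contrast strong enough that findings are solidly
visible, mirroring a clinical regime in which the full-scale detector
operates near AUROC 0.97. Datasets regenerate byte-identically from
`(n, positive_fraction, config, seed)`.

What the phantom deliberately does **not** model: real radiographic texture
and projection physics, anatomical shape variation, overlapping soft-tissue
and bowel-gas shadows, subtle non-displaced fracture appearance, and
annotation noise (phantom points are exact lesion centres). Passing tests on
phantoms therefore demonstrate that the machinery — masks, loss, training
loop, ensembling, statistics — behaves correctly and can recover planted
signal; they say nothing about clinical-grade sensitivity on real
radiographs.

## Desk-scale study conditions

The heavy experiments in the test suite run at a deliberate desk scale so
one CPU core completes them in minutes; the vignette states these sizes as
the package's chosen experimental design.

* **Synthetic recovery:** 200 phantoms at 128 px (50% positive), tiny
  backbone, fivefold cross-validation, 20 epochs, batch 4, learning rate
  3e-3, `output_level = "finest"`. Expected behaviour: every fold's best
  validation AUROC ≥ 0.85, and the fused ensemble peak falls within the
  (scaled) mask radius of a true lesion point for ≥ 80% of detected
  positives.
* **Annotation-size ablation:** nested 20% vs 100% subsets of the same
  200-image set, 12 epochs, evaluated by the 25-member ensemble on a held-out
  80-image set; full-data AUROC should be at least the 20% AUROC − 0.05
  (the full-scale counterpart rises monotonically from 0.933 to 0.973 across
  20–100% annotation budgets).

The desk-scale learning rate (3e-3) and batch size (4) differ from the
full-scale recipe (1e-5, batch 8, 100 epochs, pretrained encoder): a tiny
randomly-initialized network sees only ~800 optimizer steps in this design
and needs them; `train_config()` keeps the full-scale values as its defaults.

Numerical notes: parameters use He-scaled Gaussian initialization with the
head weights tempered (×0.1) so initial logits sit near zero (loss ≈ 4 ln 2
on empty masks); Adam uses the standard (0.9, 0.999, 1e-8) moments;
gradients are averaged within a batch; all randomness derives from one
master seed via a deterministic stream-splitting helper, so folds, epochs,
and augmentation draws are reproducible.

## Known limitations

* The full-scale backbone honours the published resolution and capacity
  contract (four levels, 32²–256² at 1024 input, 256 fusion channels) but is
  a plain strided convolutional encoder, not a layer-for-layer DenseNet-169;
  pretrained encoder weights are not bundled, so `pretrained = TRUE`
  requires a user-supplied checkpoint.
* Exact mirror equivariance is broken by stride-2 convolutions (the
  half-pixel offset), so mirroring an input changes the ensemble probability
  slightly even with the flip-containing TTA set; the effect is small on
  smooth maps and bounded in the tests.
* Training is single-threaded CPU; at the full 1024-pixel scale the forward
  pass is a few seconds per image, so full-scale *training* is out of
  desk-scale reach even though full-scale *inference* contracts are tested.
* The statistics assume one image per patient (case resampling, McNemar on
  paired calls); clustered data would need clustered resampling.
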