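---
title: "Quantifying cactus canopy cover in large orthomosaics with encoder-decoder networks"
author: "opuntiaseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cactus canopy cover in large orthomosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Orthomosaics of row-planted *Opuntia* (prickly pear) fields routinely exceed
4K resolution, far beyond what an encoder-decoder segmentation network can
ingest directly.  The workflow implemented here quantifies vegetation cover
from such mosaics by (1) splitting each image into four quadrants,
(2) rescaling the quadrants to the network's input resolution of
160 × 160 px, (3) predicting a per-pixel vegetation probability, (4)
binarising and upscaling each tile mask back to native resolution,
(5) reassembling a seam-free full-resolution mask, and (6) converting the
foreground pixel count into ground area through the pixel's ground area.
Validation uses intersection over union,

$$\mathrm{IoU} = \frac{|P \cap R|}{|P| + |R| - |P \cap R|},$$

between predicted mask $P$ and reference mask $R$, and the root mean square
error $\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (y_i - \hat y_i)^2}$ over
foreground pixel counts, where the observation units are per-tile counts
(model resolution for tile-level reporting, native-resolution quadrants for
mosaic-level reporting).  The RMSE observation unit is a genuinely open
choice — nothing in the workflow forces one — and per-tile pixel counts are
the only interpretation on which the two reporting levels are comparable,
so that is what `evaluate_tiles()` and `build_area_report()` use.

## Synthetic field scenes as ground truth

No public imagery accompanies this problem, so the package's reference data
path is a seeded scene generator (`generate_scene()`) rather than manually
annotated orthophotos.  A scene is a nadir view of a row-planted field:

* **Soil**: brown base colour modulated by low-frequency value noise
  (bilinearly upscaled 24-cell grid) plus per-pixel speckle; amplitude set
  by `soil_texture_scale`.  The texture makes colour thresholding
  imperfect, so segmentation is not trivially solvable by a 1 × 1 filter.
* **Plants**: `n_rows` horizontal furrow bands with `plants_per_row` plants
  each; every plant is 1–8 overlapping rotated ellipses ("paddles"), the
  simplest shape family with cladode-like silhouettes.  Default semi-axes
  scale with the furrow/plant spacing (8–22 % of the tighter spacing) so
  canopies stay distinct at any raster size; at the default 4000 × 2250 px
  this yields roughly 15–20 % canopy cover.
* **Shadows and illumination**: each paddle casts an offset darkened
  ellipse; a mild linear illumination ramp crosses the frame.  The oblique
  capture styles (45°/135°) are emulated by a fixed-direction horizontal
  shear about the frame centre applied identically to image and mask --
  the pipeline consumes orthophotos, so no 3-D rendering is attempted.
* **Scale**: the default ground area per pixel is 54.1950 m² / 128 959 px
  (≈ 4.2025 × 10⁻⁴ m², a GSD of about 2.05 cm), the scale of the reference
  survey mosaic, so synthetic quantification lives on the same scale as the
  field survey it emulates.  The survey's own resolution is not otherwise
  documented, so the pixel area is a free, configurable parameter.

The ground truth is exact by construction: the mask is the rendered union
of paddle ellipses and `true_area_m2 = true_foreground_px × pixel_area_m2`
holds as an identity.  What the generator does *not* reproduce: perspective
distortion, mosaicking seams and ghosting, weeds and non-crop vegetation,
senescent (non-green) cladodes, and radiometric miscalibration.  Passing
tests therefore demonstrate that the pipeline's machinery is correct and
that the networks can learn this family of scenes; they do not certify
field-ready accuracy on real UAV imagery.

## Dataset construction

`build_dataset()` reproduces the study's data path: quadrant split (a
4000 × 2250 mosaic gives four 2000 × 1125 tiles; odd dimensions give the
extra pixel to the top/left tiles), bilinear rescale of images to
160 × 160 and nearest-neighbour rescale of masks (which keeps them strictly
binary), and 4-fold augmentation of training tiles ({identity, horizontal
flip, 90° rotation, 180° rotation}), so 294 training images yield exactly
294 × 4 × 4 = 4704 training items.  Splits are made at the source-image
level; tiles of one orthophoto never straddle splits.  The flip direction
is not dictated by the augmentation scheme's description, so the common
default (horizontal) is used.  A validation subset is required by the
best-epoch checkpointing rule but its size is otherwise unspecified;
`val_fraction` defaults to 10 % of scenes and may be 0 at dataset-build
time (training then refuses to run), which keeps the 294-train/149-test
accounting of the survey campaign reproducible exactly.

## The three architectures

All three networks map `H × W × 3` inputs in [0, 1] to an `H × W`
vegetation probability map through a single-channel sigmoid head, use
'same' padding everywhere (so no crop-and-copy is needed at skip
connections), and expose `base_filters` (width), `depth` (encoder stages)
and `seed` (He-style initialisation) through `seg_model_spec()`:

* **UNet** — repeated double 3 × 3 convolution + ReLU blocks with 2 × 2 max
  pooling; a symmetric decoder of 2 × 2 up-convolutions with skip
  concatenations; filters double per stage.
* **DeepLabV3+** — a compact strided-convolution backbone (no pretrained
  encoder, for full seed reproducibility and zero external weight
  dependencies); an atrous spatial pyramid whose 3 × 3 branches use the
  dilation rates in `atrous_rates` (default 1, 6, 12, 18) plus an
  image-level pooling branch; a decoder that upsamples, concatenates a
  projected low-level feature, refines with two 3 × 3 convolutions and
  restores full resolution.
* **UNet in the Xception style** — the UNet topology with each block
  replaced by two depthwise-separable convolutions (depthwise 3 × 3
  followed by pointwise 1 × 1) and a 1 × 1 residual shortcut projection.
  A separable block is strictly lighter than its standard counterpart
  (k²·c_in + c_in·c_out vs k²·c_in·c_out weights), which is the point of
  the variant.

The layers and their gradients are implemented in single-precision C++
(`RcppArmadillo`): 3 × 3 stride-1 convolutions as nine shifted GEMMs on a
zero-padded buffer, strided/large-dilation convolutions via an im2col patch
matrix, depthwise convolutions by direct tap accumulation.  A small
reverse-mode tape in R composes them.  Analytic gradients are verified
against central differences in the test suite.

## Training protocol

`fit_segmenter()` minimises mean pixel-wise binary cross-entropy (clipped
at ε = 10⁻⁷, so the loss is bounded by −log ε) with Adam.  After every
epoch the model is evaluated on the validation tiles and the weights of the
best epoch are kept — "best" meaning highest mean per-tile validation IoU
at threshold 0.5, with validation loss as tie-breaker; IoU is the
workflow's headline metric, which is why it, and not the loss, selects the
checkpoint.  Everything is seeded: initialisation by the model spec,
shuffling by the training control; two CPU runs with identical seeds are
bit-identical.  Defaults (epochs 50, batch 16, learning rate 10⁻³) are
ordinary choices for this model family; the desk-scale experiment below
overrides them.

## Numerical and design choices

* Binarisation threshold 0.5 with ties mapped to foreground; foreground
  counts are monotone non-increasing in the threshold.
* Per-tile binarise-then-upscale (not probability upscaling), mirroring the
  mask-resizing order of the original workflow and keeping every
  intermediate raster strictly binary.
* Empty–empty IoU is defined as 1 (perfect agreement) to avoid 0/0.
* Mosaics larger than `max_tile` (default 2000 × 1125 per quadrant) are
  split recursively until tiles fit.
* Oblique shear fills exposed image columns by edge replication but fills
  masks with background, so shearing never invents vegetation.
* `run_experiment()` seeds scene *i* with `seed·1000 + i`, keeping every
  scene individually reproducible and all derived seeds far below 2³¹.

## Problem sizes used by the tests and the acceptance script

The desk-scale experiment trains all three architectures on a single CPU:
40 scenes at 800 × 448 native resolution (the full 4000 × 2250 rasters are
exercised separately in the tiling and accounting tests), 160 × 160 tiles,
base_filters 16, depth 2, batch 8, and a small fixed epoch budget (≤ 10);
on these scenes every architecture crosses held-out tile IoU 0.5 well
within that budget because colour separates the classes strongly.  The
acceptance script runs a moderately reduced end-to-end experiment (24
scenes, otherwise the desk conditions, 3 epochs) plus the survey-scale area
arithmetic and a 5-scene oracle run that isolates the tiling/rescale
quantisation error (the "model" returns the downscaled truth mask, so any
area error is attributable to the pipeline, not the network; it is well
under 5 %).

## Limitations

* The networks are desk-scale: widths and depths are an order of magnitude
  below production segmentation models, and no batch normalisation,
  dropout or pretrained backbone is used.
* Training is CPU-bound and single-threaded; wall-clock scales linearly
  with tiles × epochs.
* The synthetic generator's realism gaps (above) mean measured IoU values
  characterise the pipeline, not expected field performance.
* Plant counting / instance segmentation is out of scope, as is
  photogrammetric mosaic generation: the package consumes rasters that are
  already orthomosaics.
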