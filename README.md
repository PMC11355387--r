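# opuntiaseg

Semantic segmentation and canopy-area quantification for large orthomosaics
of row-planted *Opuntia* (prickly pear) fields.

UAV surveys of crop fields produce orthomosaics well beyond 4K resolution —
too large for an encoder-decoder network to ingest whole.  This package
implements the tiled workflow used to quantify vegetation cover in such
mosaics: split the mosaic into quadrants, rescale each tile to 160 × 160,
predict a per-pixel vegetation probability with one of three architectures
(UNet, DeepLabV3+, or a depthwise-separable UNet in the Xception style),
binarise, upscale each tile mask back to native resolution, reassemble a
seam-free full-resolution mask, and convert the foreground pixel count into
ground area.  Validation uses intersection over union,

    IoU = |P ∩ R| / (|P| + |R| − |P ∩ R|),

against a reference mask, and RMSE over per-tile foreground pixel counts,

    RMSE = sqrt( (1/n) Σᵢ (yᵢ − ŷᵢ)² ).

Because no public imagery exists for this problem, the package ships a
seeded synthetic-field generator whose scenes carry *exact* ground truth
(the mask is the rendered union of canopy ellipses), replacing the manual
annotation path end to end.  The convolutional layers and their gradients
are implemented in C++ via RcppArmadillo — no external deep-learning
framework is needed; training runs on a single CPU.

It is aimed at precision-agriculture researchers who want a fully
reproducible, dependency-light reference implementation of the
large-mosaic segmentation workflow, and at anyone who needs the building
blocks (quadrant tiling with exact reassembly, paired augmentation,
mask-level metrics) for similar pipelines.

## Worked example

```r
library(opuntiaseg)

# simulate a small survey: 12 scenes, train the three networks, quantify
res <- run_experiment(list(seed = 1L,
                           scene = list(n_scenes = 12L),
                           model = list(depth = 2L),
                           train = list(epochs = 2L)))
res$report
#> Vegetation area report
#>          model pixel_count area_m2    iou      rmse
#>           unet      15,375  6.4613 0.2829 9713.4782
#>  deeplabv3plus      53,230 22.3699 0.8040  481.8182
#>  unet_xception      48,012 20.1770 0.5746 1548.7977
#>      reference      54,049 22.7141 1.0000    0.0000
```

Each row is one trained model applied to a held-out synthetic survey
mosaic: its vegetation pixel count, the implied area in m² (pixel count ×
ground area per pixel, here the survey scale 54.1950 m²/128 959 px ≈ 4.2 ×
10⁻⁴ m²), the mosaic-level IoU against the exact ground-truth mask, and the
RMSE over per-quadrant pixel counts.  The reference row is the ground truth
itself (IoU 1, RMSE 0).  At this deliberately tiny budget (12 scenes, 2
epochs) DeepLabV3+ has already converged while UNet has not — with the
default desk configuration (40 scenes, see
`experiment_config()`) all three models reach IoU well above 0.5.

Individual stages are exported too:

```r
sc  <- generate_scene(scene_params(seed = 7))        # 4000 x 2250 scene
ds  <- build_dataset(lapply(1:6, function(i)
         generate_scene(scene_params(width_px = 800, height_px = 448,
                                     n_rows = 4, plants_per_row = 8,
                                     seed = i))), model_size = 160)
fit <- fit_segmenter(ds, "unet_xception",
                     spec = seg_model_spec("unet_xception", base_filters = 16,
                                           depth = 2),
                     control = train_control(epochs = 3, batch_size = 8))
mp  <- predict(fit, sc$image)                        # full-mosaic mask
area_from_count(count_foreground(mp$full_mask), sc$image$pixel_area_m2)
```

A thin command-line front end (`inst/cli/opuntiaseg`) exposes
`simulate`, `prepare`, `train`, `segment`, `quantify` and `run`.

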