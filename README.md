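# mihcseg

Analysis of brightfield **multiplex immunohistochemistry (mIHC)** image
patches in R. One tissue section, six chromogen-labelled cell populations —
yellow CD3, teal CD4, purple CD8 T-cells, red CD20 B-cells, black CD16
myeloid cells, brown (DAB) K17 tumor cells — over a blue hematoxylin
counterstain. `mihcseg` is for image-analysis folks and computational
pathology researchers who need to unmix those colours, classify cells from
cheap dot annotations, and quantify tumor-immune spatial relationships,
without multispectral imaging hardware.

## What is inside

* **Beer-Lambert stain model.** Optical density $OD = -\log(I/I_0)$ is
  additive over stains: $OD = \sum_s c_s v_s$. `rgb_to_od()`, `od_to_rgb()`,
  `render_beer_lambert()`, and `deconvolve_linear()` — the exact per-pixel
  least-squares inversion, valid for up to three stains (beyond three the
  system is underdetermined).
* **ColorAE** (`train_colorae()`): a convolutional autoencoder predicting an
  8-channel concentration map (6 stains + hematoxylin + background), trained
  with a Beer-Lambert reconstruction loss plus a label-consistency loss that
  re-renders each weakly labelled pixel from its labelled stain channel.
  `concentrations_to_masks()` thresholds concentrations (per-channel Otsu by
  default) into per-class masks.
* **U-Net** (`train_unet()`): a compact encoder-decoder with skip
  connections, trained on superpixel weak labels with inverse-frequency
  weighted cross-entropy and dropout.
* **Weak labels** (`compute_superpixels()`, `seeds_to_superpixel_labels()`,
  `seeds_to_disk_labels()`): SLIC-style superpixels painted by seed (dot)
  annotations; seed dilation into disks (10.5 µm lymphocyte diameter for
  evaluation, 2 µm for the conservative training baseline).
* **Ensembles** (`mask_union()`, `mask_intersection()`, `union_anchor()`,
  `ensemble_masksets()`): the four ColorAE:U-Net mask combination operators.
* **Evaluation** (`dice()`, `ssim()`, `match_detections()`,
  `aggregate_and_score()`, `metric_report()`): DICE
  ($2|A\cap B|/(|A|+|B|)$), windowed SSIM, and the dilated-seed detection
  protocol — TP/FP/FN counted between mask connected components and seed
  disks, pooled across patches into precision / recall / F1.
* **Spatial statistics** (`extract_components()`, `nearest_neighbor()`,
  `proximity_histogram()`, `tile_aggregate()`, `count_masks()`,
  `restrict_to_region()`): exact edge-to-edge nearest-neighbour distances
  (NNDist, asymmetric by construction), distance-band proximity counts, and
  2000-px-tile aggregation.
* **Synthetic data** (`synth_spec()`, `generate_patch()`,
  `generate_dataset()`): seeded mIHC patches with complete ground truth
  (label map, per-class masks, centroid seeds, true concentrations), so the
  whole pipeline is testable end to end without clinical slides.

A thin command-line front-end (`inst/cli/mihc.R`, subcommands `synth`,
`labels`, `train-colorae`, `train-unet`, `infer`, `ensemble`, `evaluate`,
`spatial`) drives the same functions from a shell. See
`vignettes/mihcseg-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

Generate synthetic patches, train both models briefly, ensemble their masks
and evaluate:

```r
library(mihcseg)

pal <- generate_palette(seed = 1)

# exact linear unmixing for <= 3 stains (noiseless roundtrip)
sub <- stain_palette(pal$names[c(1, 3, 6)], pal$od_vectors[, c(1, 3, 6)])
set.seed(1)
conc <- array(runif(64 * 64 * 3), c(64, 64, 3))
img <- render_beer_lambert(conc, sub, noise_sd = 0)
max(abs(deconvolve_linear(img, sub) - conc))
#> [1] 5.192513e-14

# 30 patches at 0.7 um/px with ground truth + superpixel weak labels
spec <- synth_spec(height = 64, width = 64, pixel_size = 0.7, seed = 1,
                   n_cells = c(CD3 = 2, CD4 = 2, CD8 = 2, CD20 = 1, CD16 = 3),
                   cell_radius_um = list(CD3 = c(2.8, 4.2), CD4 = c(2.8, 4.2),
                                         CD8 = c(2.8, 4.2), CD20 = c(2.8, 4.2),
                                         CD16 = c(3, 4.5)),
                   nest_radius_um = c(3, 6))
train <- lapply(1:30, function(i) {
  sp <- spec; sp$seed <- i
  p <- generate_patch(sp, pal)
  seg <- compute_superpixels(p$image, target_segment_size_px = 100)
  list(image = p$image,
       labels = suppressWarnings(seeds_to_superpixel_labels(seg, p$truth$seeds)),
       truth = p$truth)
})

cae <- train_colorae(train[1:25], pal, train_config(epochs = 6, seed = 1))
un  <- train_unet(train[1:25], train_config(epochs = 6, seed = 1))
tail(cae$log, 1)
#>   epoch   rec_loss label_loss
#> 6     6 0.02131843 0.02495831

held <- train[26:30]
pred_cae <- lapply(held, function(s)
  concentrations_to_masks(colorae_forward(cae$model, s$image), pixel_size = 0.7))
pred_un <- lapply(held, function(s)
  probs_to_masks(unet_forward(un$model, s$image), pixel_size = 0.7))
union <- lapply(seq_along(held), function(i)
  ensemble_masksets(pred_cae[[i]], pred_un[[i]], "union"))

disks <- lapply(held, function(s)
  seeds_to_disk_labels(s$truth$seeds, 64, 64, diameter_um = 10.5,
                       pixel_size_um = 0.7))
metric_report(union, disks, lapply(held, function(s) s$truth$masks))
#>   class tp fp fn precision recall        f1      dice
#> 1   CD3 11 40  0 0.2156863      1 0.3548387 0.3861111
#> 2   CD4 10  5  0 0.6666667      1 0.8000000 0.7349537
#> 3   CD8 10  0  0 1.0000000      1 1.0000000 0.9391796
#> 4  CD20  5  0  0 1.0000000      1 1.0000000 0.9418133
#> 5  CD16 16  3  0 0.8421053      1 0.9142857 0.7858942
#> 6   K17  5  5  0 0.5000000      1 0.6666667 0.7959900
```

Six epochs already give perfect recall with moderate precision (the union
operator is the recall-oriented ensemble; precision rises with longer
training and with the `intersection` / `union_anchor` operators — the
acceptance run below trains 12 epochs on 200 patches). Spatial statistics
run on any mask set:

```r
tab <- extract_components(union[[1]], pixel_size = 0.7)
nearest_neighbor(tab, "CD16", "K17")$distance_um
#> [1] 16.34  7.31  0.00
```

— each CD16 myeloid component's edge-to-edge distance (µm) to the nearest
K17 tumor nest; 0 means touching/overlapping.

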