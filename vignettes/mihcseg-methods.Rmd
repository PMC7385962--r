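---
title: "Models and methods behind mihcseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mihcseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mihcseg)
```

# The problem

Brightfield multiplex immunohistochemistry (mIHC) labels six or more cell
populations on one tissue section with distinctly coloured chromogens — in
the panel this package models: yellow CD3, teal CD4, purple CD8, red CD20,
black CD16, brown (DAB) K17 — over a blue hematoxylin counterstain and a grey
background. Quantitative analysis needs three things that `mihcseg`
provides: (1) unmixing of the observed RGB colour into per-stain
concentrations, (2) per-pixel classification of cells from cheap dot ("seed")
annotations, and (3) spatial statistics of the resulting masks (counts,
areas, nearest-neighbour distances to tumor nests).

# The Beer-Lambert stain model

Transmitted light through absorbing stains follows the Beer-Lambert law.
After mapping intensities to optical densities,
$OD = -\log(I / I_0)$ (natural log throughout; any fixed base is equivalent
up to a rescaling of the stain vectors), absorption is linear:
$OD(x) = \sum_s c_s(x)\, v_s$, with $c_s \ge 0$ the concentration of stain
$s$ at pixel $x$ and $v_s$ its OD colour vector. With at most three stains
the $3 \times K$ system is determined and `deconvolve_linear()` solves it per
pixel by least squares, clipping negative solutions to zero (simpler than a
constrained solve and adequate at the noise levels used). With more stains
the system is underdetermined — that regime is what the autoencoder is for.

Numerical choices: intensities live in $[0,1]$ internally (8-bit I/O is
converted on read/write); before the log they are floored at $\varepsilon =
1/255$ of the white point so saturated pixels stay finite. For real images
the white point would be estimated per channel as the 99th-percentile
intensity (overridable); synthetic palettes simply carry $I_0 = (1,1,1)$.

# ColorAE: the colour-decomposition autoencoder

`train_colorae()` fits a convolutional encoder-decoder that maps an RGB patch
to an 8-channel nonnegative concentration map (6 stains + hematoxylin +
background; softplus output). Two losses are combined:

* **Reconstruction**: MSE between the input and the Beer-Lambert re-rendering
  of the predicted concentrations, in intensity space (the reconstruction the
  model is asked to match is the image itself, not its OD transform).
* **Label consistency** (weight $\lambda$, default 1): each weakly labelled
  pixel is re-rendered using only its labelled stain channel plus
  hematoxylin, and background-labelled pixels using hematoxylin plus the
  background channel; MSE over labelled pixels.

The label loss resolves the decomposition ambiguity that reconstruction
alone leaves with more than three stains. Two asymmetries in the channel
masking are deliberate:

* Hematoxylin is always allowed because the counterstain underlies every
  nucleus; without it counterstained pixels are unreconstructable from a
  single stain channel.
* The background channel is *not* always allowed. Its OD vector is a small
  grey, so an unbounded background concentration acts as free "grey ink":
  mixtures of hematoxylin and background can reproduce the black CD16 vector
  exactly, and in early experiments the optimiser exploited exactly that
  shortcut (background concentrations of 5-15 inside cells, stain channels
  dead, CD16/K17 masks empty). Restricting the background channel to
  background-labelled pixels restores identifiability; dominant-stain
  accuracy on held-out synthetic patches rose from ~0.6 to ~0.98.

Assigning eight output channels to eight colour roles is a combinatorial
problem that gradient descent from a random start solves only sometimes: at
roughly half of the training seeds one stain channel (typically one whose OD
vector lies close to hematoxylin's — purple CD8 and hematoxylin are only
~23° apart) lost the early competition for its colour, drifted into softplus
saturation, and produced empty masks forever after. Four choices make
training reliable across seeds:

* **Channel-routing bootstrap.** At a weakly labelled pixel only two
  channels are allowed ({label stain, hematoxylin}, or {hematoxylin,
  background} on background), so the Beer-Lambert system is overdetermined
  and the same per-pixel least-squares fit that `deconvolve_linear()` uses
  yields an explicit concentration target (clipped to a physical ceiling of
  3, because a dark pixel mislabelled background otherwise blows the
  restricted fit up to absurd background concentrations). The first quarter
  of the epochs regresses the network directly onto these targets, routing
  every channel deterministically from any initialisation; the
  reconstruction and label-consistency losses take over afterwards and
  refine where the rigid two-channel fit is wrong (overlaps, compound
  colours). The ≤3-stain exact solver thus bootstraps the many-stain
  network.
* The output layer's bias starts at $-3$ (near zero concentration on the
  live side of the softplus); starting at softplus(0) renders far too dark
  an image and the violent "push everything down" phase saturates the
  output irrecoverably.
* The output layer's channel columns are initialised orthogonally, so no
  channel starts entangled with another's colour direction.
* Adam runs with $\epsilon = 10^{-4}$ rather than the customary $10^{-8}$: a
  suppressed channel emits a vanishing but consistent negative gradient,
  which a small $\epsilon$ renormalises into full-size steps that march the
  pre-activation tens of units into saturation.

Masks are derived from concentrations by `concentrations_to_masks()`: pixel
$x$ belongs to stain $s$ iff $c_s(x) \ge \tau_s$ and $s$ is the argmax over
the six stain channels. $\tau_s$ defaults to a per-channel Otsu threshold on
the concentration histogram; components smaller than the pixel area of a
3 µm disk are removed (post-filtering of sub-cellular specks).

# U-Net on superpixel weak labels

Seed annotations (one dot per cell) are turned into per-pixel weak labels by
SLIC-style superpixels (`compute_superpixels()`): k-means in colour+space
with compactness 10, colour channels scaled to 0-100, target segment size
defaulting to the squared lymphocyte diameter in pixels, and a
connectivity-enforcement pass (each connected region of the assignment
becomes a segment; fragments below a quarter of the target size merge into
the neighbour with the longest shared border). Every segment containing a
seed takes the seed's class; the rest is background. If one segment catches
seeds of two classes, the seed nearest the segment centroid wins and a
warning reports the conflict (the algorithm choice and the tie-break are
package decisions; no particular superpixel algorithm is canonical here).
Hematoxylin-only pixels are background for these labels; only the
autoencoder carries hematoxylin as a channel of its own.

`train_unet()` fits a compact U-Net — two pooling levels with skip
connections, base width 16, dropout 0.2 at the bottleneck (training only) —
with weighted cross-entropy, weights inverse to class frequency normalised
to mean 1 (absent classes get 1). The weighting matters twice: the class
profile is imbalanced by design, and weak labels systematically miss the
~15-25% of cell area falling in seedless superpixels, so background labels
on cell-coloured pixels must be cheap to override. A deeper, wider U-Net is
standard on real tissue; at the 64-256 px patch sizes this package targets,
depth 2 already covers the receptive field the synthetic task needs and
keeps CPU training in minutes. Augmentation uses flips and 90° rotations
only — colour jitter would corrupt the stain signal the model must learn.

Both networks run on a small self-contained convolutional engine
(im2col convolutions with exact backpropagation, Adam, seeded end to end;
single-threaded deterministic CPU training). The backward passes are
verified against finite-difference gradients of the actual training losses
in the test suite.

# Ensemble operators

Per class, the ColorAE and U-Net masks are combined by four operators:
union (pixelwise OR), intersection (pixelwise AND), and two anchored unions
— union components that contain at least one anchor-model pixel are kept,
the rest discarded (`union_anchor(colorae, unet)` anchors on ColorAE and
vice versa). Connected components use 8-connectivity, shared as one routine
across the ensemble, evaluation and spatial modules so the adjacency
convention cannot drift. Classes are combined independently and cross-model,
cross-class overlap is preserved: a pixel may legitimately carry two labels
(compound colours from co-expressed markers).

The operators themselves are pure pixel algebra; in the evaluation pipeline
their outputs pass through the same sub-cell-size post-filter as the
single-model masks, because intersecting two filtered masks can leave
fragments smaller than any cell (post-filtering predictions below the
cell-size threshold is part of the method's standard post-processing).

# Evaluation protocols

* **DICE**: $DSC = 2|A\cap B| / (|A| + |B|)$. Two empty masks score 1
  (perfect agreement on absence), flagged with a warning.
* **SSIM**: Gaussian-weighted sliding windows (size 11, $\sigma = 1.5$,
  $k_1 = 0.01$, $k_2 = 0.03$ — the standard published constants), windows
  fully inside the image.
* **Dilated-seed detection**: seeds are dilated to disks (diameter 10.5 µm
  by default, the average lymphocyte; radius `round(d/2/pixel_size)` px —
  exactly 30 px at 0.175 µm/px). TP = mask components overlapping ≥ 1 disk,
  FP = components overlapping none, FN = disks overlapping no mask pixel.
  Overlap means ≥ 1 shared pixel. The counting is the literal
  component/disk definition, not one-to-one matching: a component spanning
  two disks is one TP and clears both disks. Counts pool additively across
  patches before precision/recall/F1; undefined ratios are reported as NA,
  never silently 0.

# Spatial statistics

Nearest-neighbour distance (NNDist) is edge-to-edge: the minimum Euclidean
distance between pixel centres of a source component and any pixel of the
target class, computed exactly via a Euclidean distance transform of the
target union and validated against an all-pairs brute force in the tests.
Overlap gives 0; 8-adjacent components give 1 or √2 px. The measure is
asymmetric (immune→tumor ≠ tumor→immune). Proximity histograms count
records in half-open distance bins (default 10 µm). Tile aggregation
assigns records to square tiles (default 2000 px) by source centroid,
takes a per-tile median and then a cross-tile mean; both statistics are
configurable because whole-slide practice mixes per-tile medians with
cross-tile averaging, and pooled medians are also of interest.

# The synthetic-data generator

`generate_patch()` emulates a high-density tumor region: lymphocytes as
near-circular disks, CD16 as irregular rotated ellipses with boundary
wobble, K17 tumor nests as merged irregular blobs carrying hematoxylin
nuclear "holes" where the K17 concentration drops to 15% — the
nuclear-exclusion failure mode that colour-based segmentation shows on real
tumor nuclei. Cells carry a flat stain concentration drawn from
[0.6, 1.2], hematoxylin nuclei cover ~35% of each cell's area, the
background channel adds a constant grey cast (0.12), rendering is
Beer-Lambert with additive Gaussian intensity noise (sd 0.01), and a few
hematoxylin-only stromal nuclei land on the background. The default class
profile is imbalanced (myeloid-rich, B-cell-poor) to exercise the class
weighting. Same-class cells never touch (each labelled component carries
exactly one seed); cells of different classes may overlap at a low
configurable rate, and objects may clip the patch border as real cells do.
Ground truth is complete: label map, per-class masks, per-cell centroid
seeds and the true concentration field.

What the generator does **not** emulate: tissue texture inside cells,
scanner artifacts and illumination gradients, chromogen co-localisation
chemistry, crowded nuclear overlap, or the stain variability of real slides.
Green-field performance numbers on these patches are therefore upper bounds;
passing tests demonstrate the correctness and internal consistency of the
pipeline, not clinical-grade accuracy.

# Problem sizes and reproducibility

The bundled experiments (test suite and `scripts/acceptance.R`) run at desk
scale, chosen as sizes a laptop CPU handles in minutes: 64×64 px patches at
0.7 µm/px (a 44.8 µm field, so whole lymphocytes of 5.6-8.4 µm fit; at the
native 0.175 µm/px scan resolution a 64 px patch could not contain one
cell), 200 training and 50 held-out patches, 12 epochs per model. Every
random stream — palette jitter, cell placement, network initialisation,
shuffling, dropout, augmentation — is seeded, and training is
single-threaded, so runs are reproducible end to end. Larger patches
(including the native 1920×1200 at 0.175 µm/px) are supported via
`tile_image()`/`stitch_masks()`.

# Known limitations

* The linear solver is restricted to ≤ 3 stains by design; it exists as the
  exact baseline and roundtrip oracle, not as the mIHC workhorse.
* Otsu thresholds are computed per patch; on a patch genuinely lacking a
  class the threshold splits noise, and only the minimum-area filter guards
  against spurious specks. Thresholds can be frozen from a reference set.
* Instance segmentation (splitting touching same-class cells) is out of
  scope; the detection protocol counts components, not cells.
* Nearest-neighbour distances are exact for pixelated masks; sub-pixel
  boundary geometry is not modelled.
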