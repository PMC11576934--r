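---
title: "Hetero-modal, resolution-independent sub-segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hetero-modal, resolution-independent sub-segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hyposeg)
```

## The problem

The hypothalamus and its adjacent structures (fornix, optic system,
hypophysis, epiphysis) are small, thin and low-contrast; segmenting them
from brain MRI benefits from combining a T1-weighted and a T2-weighted
image, but in practice one of the two contrasts is often missing, and
cohorts differ in voxel size (0.7-1.1 mm isotropic). `hyposeg`
implements a single segmentation model that addresses both problems at
once:

* **hetero-modal**: the network accepts T1-only, T2-only or T1+T2 input
  through one set of weights, and
* **voxel-size-independent**: the network normalizes its internal
  feature maps to a fixed 1.0 mm base resolution, so one model serves
  acquisitions at different voxel sizes.

The segmentation target is a 24-structure lookup table
(`hypothalamusLUT()`): anterior/middle/posterior hypothalamic
sub-regions, the optic structures and adjacent structures, with nine
lateral L/R pairs.

## The network

Each of three 2D fully convolutional networks (one per anatomical plane)
follows a U-Net layout of five *competitive dense blocks* (CDBs) per arm
separated by a bottleneck CDB. A CDB is four sequences of PReLU →
3×3 convolution → batch normalization whose intermediate outputs
compete by elementwise maximum instead of concatenating; in the first
two encoder blocks the leading PReLU is replaced by a BN that normalizes
the inputs. Competition keeps channel counts constant, which is what
keeps the parameter budget small.

Three design elements sit on top of this backbone:

* **Modality-specific input blocks and fusion.** T1 and T2 stacks are
  first processed by separate input CDBs. Their feature maps are merged
  by a learnable normalized weighted sum
  \[ F_{fused} = \frac{|w_{T1}|}{|w_{T1}|+|w_{T2}|} F_{T1} +
     \frac{|w_{T2}|}{|w_{T1}|+|w_{T2}|} F_{T2}, \]
  with both global scalar weights initialized at 0.5. The coefficients
  always sum to one; setting a weight to zero removes that modality
  exactly, so a missing modality at inference reproduces the remaining
  branch bit for bit (`fuseFeatureMaps()`). Absolute values make sign
  flips during optimization harmless.
* **Resolution-normalization.** The first scale transition interpolates
  the fused native-resolution feature maps to the 1.0 mm base
  resolution with scale factor `s = native/base` (bilinear, half-pixel
  centre convention, output size `round(H*s)`); the last transition
  interpolates back. The pre-normalization grid size is recorded on the
  way down and restored exactly on the way up: `round()` is not
  injective, so a metadata-free arithmetic inverse cannot exist for all
  sizes, and carrying the size is also what the network needs to emit
  logits on the native grid.
* **2.5D view aggregation.** Axial, coronal and sagittal networks
  predict independently from 7-slice stacks; their softmax maps are
  averaged with weights 0.4/0.4/0.2 and renormalized
  (`aggregateViews()`). The sagittal network cannot see lateralization,
  so it is trained on the laterally merged table (24 → 15 classes,
  `mergeLateralLabels()`); before aggregation each merged probability is
  copied to both lateral descendants (`unmergeSagittal()`). Copying
  (rather than halving) keeps the fixed view weights meaningful; the
  single renormalization inside the aggregation restores the simplex.

Remaining wiring that the lineage leaves open was fixed as follows:
2×2 max-pooling with index-preserving unpooling; skip connections
compete by maxout at the base-resolution scales; at the native scale the
decoder carries `inner_channels` while the encoder skip has
`outer_channels`, so that one skip is fused by channel concatenation
into the last decoder block; the classifier is a 1×1 convolution
and softmax is applied at inference; argmax ties break to the lowest
class index. With the widened hetero-modal configuration (80 channels in
the base-resolution CDBs, 64 in the native ones) this realization counts
2.50 M trainable parameters, and 1.40 M for the narrow single-modality
baseline (64/32) — both a few percent below the approximate budgets the
architecture family reports for itself, which round generously.

The whole network, including reverse-mode differentiation and AdamW, is
implemented in this package (R with C++ kernels for convolution and
pooling); every layer gradient is verified against finite differences in
the test suite.

## Training procedure

`trainNetwork()` follows the published recipe, whose values are the
`trainConfig()` defaults: 100 epochs, batch size 16, AdamW with weight
decay 1e-4, learning rate 0.05 stepped to 0.005 after 70 epochs, and a
combined loss of median-frequency-weighted cross-entropy
(`medianFrequencyWeights()`: `w_c = median(f)/f_c`, zero-count classes
get weight 0; the weighted *mean* over pixels, the convention of the
lineage's framework) plus soft Dice over the classes present in the
target (`1 - mean_c 2\sum pg / (\sum p + \sum g + 1e-6)`, equal sum of
the two terms). The Dice mean includes the background class: with
median-frequency weights the background CE weight is tiny, and the
background Dice term is what keeps foreground false positives in
check — without it the optimum of the loss grows a one-voxel
over-segmentation halo around every small structure.

*Modality dropout* makes the model hetero-modal: after 10 warm-up epochs
each training example draws one of {T1+T2, T1-only, T2-only} uniformly;
a dropped modality's branch is skipped and its fusion weight is zero for
that example. Augmentations: random affine (translation ±15 mm,
rotation ±10°, uniform scale 0.85–1.15; labels
nearest-neighbour, edge-value fill), a multiplicative bias field
`exp(P(x))` with an order-3 polynomial whose coefficients are uniform in
±0.5, internal scale augmentation (the resolution-normalization
factor is jittered by U(0.85, 1.15), sampled per batch), and optional
external scale augmentation that resamples the example to a voxel size
drawn from a configurable range, emulating acquisition at another
resolution. One RNG stream per concern is derived from the master seed,
so runs are bitwise reproducible on one CPU thread.

## Evaluation metrics

`diceCoefficient()`, `volumeSimilarity()` and `hd95()` follow the
standard definitions; for all mask pairs `0 <= Dice <= VS <= 1`. HD95 is
computed over border voxels (6-connectivity erosion difference) with
distances in mm (anisotropy-aware) and the 95th percentile taken with
linear interpolation between order statistics; identical masks give
exactly 0, and an empty mask raises an undefined-metric error rather
than silently reporting 0. Both-empty Dice/VS pairs are defined as 1,
empty-versus-nonempty as 0. `iccA1()` is the two-way, absolute-agreement,
single-measure intraclass correlation from the ANOVA mean squares, with
the standard F-based 95% interval; `pairedComparison()` wraps the paired
two-sided Wilcoxon signed-rank test with Bonferroni correction and flags
the all-zero-difference case as degenerate. `evaluatePair()` aggregates
per-structure rows into unweighted region-group and global means,
excluding structures absent from both maps.

## The phantom generator

No MRI ships with this package; `generatePhantom()` builds co-registered
pseudo-T1/T2 pairs with ground truth from a continuous scene defined in
mm: a midline ventricle-like ellipsoid with inverted contrast between
the channels (dark in T1, bright in T2 — the property fusion can
exploit), a mirrored pair of low-contrast nucleus-like spheres, a
mirrored pair of thin optic-tract-like tubes, and a midline
commissure-like rod. Structures have a soft partial-volume edge (0.8 mm)
crossing 0.5 exactly on the continuous surface, so rasterized volumes
match analytic volumes and the same scene can be rasterized at 0.8 and
1.0 mm with consistent physical volumes (`generateMultiresPair()`).
Additive Gaussian noise (sd 0.04) and a mild multiplicative bias field
(order-3 polynomial, coefficients ±0.05, giving fields mostly
within ±10% across the field of view — the inhomogeneity scale of
uncorrected research MRI) emulate intensity nonuniformity;
`makeDataset()` jitters structure centres (±1.2 mm) and sizes
(±10%), mirroring lateral pairs jointly, and splits
deterministically into training and validation collections. Structure
sizes and channel contrasts are chosen so that the ground truth is
recoverable from the images (every structure at least ~2 voxels of
radius at 0.8 mm, class means several noise standard deviations apart):
a scene whose labels cannot be recovered even in principle would make
segmentation experiments meaningless.

What the phantoms deliberately do not model: MRI physics (no k-space or
sequence simulation), anatomy-shaped backgrounds, defacing artefacts, or
population demographics. Tests passing on phantoms therefore demonstrate
the *mechanics* of the pipeline — fusion, resolution independence,
missing-modality robustness, metric correctness — not clinical-grade
accuracy on real MRI.

## The scaled-down replication experiments

The published experiments run at GPU scale (three planes, 80/64
channels, 100 epochs, hundreds of annotated scans). The package's
acceptance suite replays the two central experiments at desk scale, one
CPU, in minutes, with these choices:

* one coronal network, 16 inner / 16 outer channels, trained for 20
  epochs on 8 phantoms (32³ at 0.8 mm), evaluated on 4 held-out
  phantoms;
* the learning-rate step keeps the published schedule fraction (the
  drop happens after 70% of the epochs, i.e. epoch 14 of 20) but the
  absolute rates are re-scaled to the toy regime (0.03 stepped to
  0.003): the published 0.05 is tuned for tens of thousands of
  optimizer steps and oscillates over the 320 steps of the toy budget.
  Modality dropout starts after 10 epochs (the module default);
* the affine translation range is scaled to the phantom field of view
  (±1.5 mm ≈ 6% of 25.6 mm, the same fraction the published
  ±15 mm is of a head-sized field of view); rotation, scaling and
  bias ranges are unchanged;
* external scale augmentation over 0.7–1.1 mm (the resolution range the
  tool targets) is enabled so the cross-resolution evaluation at 1.0 mm
  stays inside the training distribution, as in the generalizability
  arm of the published protocol.

The missing-modality experiment then checks that T1+T2 input reaches a
mean foreground Dice of at least 0.80 on held-out phantoms and that
T1-only input stays within 0.10 of it; the generalizability experiment
rasterizes the same held-out scenes at 1.0 mm and checks that Dice drops
by at most 0.10 relative to 0.8 mm.

## Numerical choices and degenerate inputs

* `conform()` reorients by permutation/flips only (no resampling),
  prefers the sform, refuses shear above 1e-3 and singular affines, and
  rescales intensities to [0,1] by robust min-max (0.1/99.9
  percentiles); a constant image maps to zeros; volumes already
  canonical and in [0,1] pass through unchanged, making conform
  idempotent. Label volumes are never rescaled.
* Slice stacks replicate edge slices at the borders (no fabricated
  zero-intensity tissue); stack thickness defaults to 7 and must be odd.
* Pooling uses floor mode; decoder unpooling scatters onto the recorded
  argmax positions. Maxout ties route to the first operand.
* Batch-norm eval mode uses running moments, so inference is
  deterministic; an all-constant channel gives zero variance and is
  guarded by the usual 1e-5 epsilon.
* The fusion module raises distinct errors for both-absent inputs,
  shape mismatches, and two zero weights with both modalities present.
* Checkpoints store config, plane, and a lookup-table fingerprint and
  refuse to load against a different table or plane.

## Known limitations

* The exact CDB wiring of the published architecture family is cited,
  not restated, in its papers; this package fixes one concrete
  realization (documented above) whose parameter count lands within a
  few percent of the published approximate budgets.
* Training at the published scale (100 epochs, 80/64 channels, three
  planes, real MRI) is out of desk-scale reach in R on one CPU; the
  package trains toy configurations in minutes and the full
  configuration is exercised structurally (build, forward, count).
* Phantom realism is intentionally limited (see above); no claims about
  accuracy on real MRI follow from the shipped experiments.
* Partial-volume-compensated volume estimation, eTIV normalization and
  registration are out of scope; volumes are plain voxel counts times
  voxel volume.
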