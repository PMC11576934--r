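# hyposeg

Hetero-modal, resolution-independent sub-segmentation of the
hypothalamus and adjacent structures from brain MRI, for neuroimaging
researchers who need one model that accepts T1-weighted and/or
T2-weighted input at different voxel sizes (0.7–1.1 mm isotropic) and
returns a 24-structure parcellation with reliability metrics.

## What is inside

The core is a 2.5D hetero-modal, voxel-size-independent F-CNN
(`buildFCNN()`): per anatomical plane, a U-Net of five competitive dense
blocks (PReLU–Conv3×3–BN ×4, elementwise-maximum dense connections) per
arm plus a bottleneck. T1 and T2 are encoded by modality-specific input
blocks and merged by a learnable normalized fusion

    F_fused = |w_T1|/(|w_T1|+|w_T2|) * F_T1 + |w_T2|/(|w_T1|+|w_T2|) * F_T2

so a missing modality (weight forced to 0) reproduces the remaining
branch exactly. Network-integrated resolution-normalization interpolates
feature maps between the native voxel size and a 1.0 mm internal base
resolution, making the model independent of acquisition resolution.
Axial/coronal/sagittal predictions are ensembled by a 0.4/0.4/0.2
weighted average; the sagittal network works on the laterally merged
label set (24 → 15) and its probabilities are copied back to both
lateral classes before aggregation.

Training (`trainNetwork()`) uses median-frequency-weighted cross-entropy
plus soft-Dice loss, modality dropout (uniform over input combinations
after a warm-up), affine/bias-field/scale augmentation, and AdamW with a
step learning-rate schedule — the complete network, autodiff and
optimizer are implemented in the package (R + C++ kernels). The metric
suite covers Dice, volume similarity, 95th-percentile Hausdorff distance
(mm, anisotropy-aware), ICC(A,1) with 95% CI, and paired Wilcoxon tests
with Bonferroni correction. A synthetic phantom generator
(`generatePhantom()`, `makeDataset()`) produces co-registered
two-contrast volumes with ground truth at configurable voxel sizes for
end-to-end testing without any MRI data.

## Worked example

```r
library(hyposeg)

lut <- toyLUT()                                   # 6-label toy scene
ds  <- makeDataset(12, phantomSpec(voxelSize = 0.8), seed = 101)

cfg <- networkConfig(n_classes = nClassesFor(lut, "coronal"),
                     inner_channels = 16, outer_channels = 16)
net <- buildFCNN(cfg, "coronal", lut, seed = 1)
countParameters(net)
#> [1] 113525

tc <- trainConfig(epochs = 20, seed = 1, lr_initial = 0.03, lr_late = 0.003,
                  lr_switch_epoch = 14,
                  affine_translation_mm = c(-1.5, 1.5),
                  external_scale_range = c(0.7, 1.1))
fit <- trainNetwork(net, ds$train, tc, lut)       # ~7 min on one CPU

v   <- ds$validation[[1]]
res <- segment(v$t1, v$t2, list(coronal = fit$net), lut)
head(structureVolumes(res), 3)
#>   label_id      name              region voxel_count volume_mm3
#> 1        1 Ventricle              others         625    320.000
#> 2        2 L-Nucleus hypothalamic-middle         423    216.576
#> 3        3 R-Nucleus hypothalamic-middle         414    211.968

rep <- evaluatePair(labelMap(res), v$labels, lut)
metricAggregates(rep)
#>                 level      dice        vs   hd95_mm
#> 1              others 0.7745195 0.7745195 0.9656854
#> 2 hypothalamic-middle 0.8558082 0.8558082 0.8000000
#> 3               optic 0.9097927 0.9097927 0.8000000
#> 4              global 0.8467068 0.8467068 0.8552285
```

The trained toy model recovers every structure (here Dice equals volume
similarity because the reference lies inside the slightly dilated
prediction) with sub-voxel boundary error (HD95 about one 0.8 mm
voxel).

`structureVolumes()` reports plain voxel-count volumes (count × voxel
volume in mm³) per structure; `evaluatePair()` prints per-region and
global Dice / volume similarity / HD95 against a reference labelling.
Dropping `t2` from the `segment()` call runs the same trained model
T1-only through the fusion module.

A command-line wrapper with `simulate | train | predict | evaluate`
subcommands is installed under `inst/cli/hyposeg`; see the vignette.

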