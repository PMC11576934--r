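# Shared fixtures, all generated in code at test time.

# small network config that survives the four pooling stages at >= 24^2
tinyNetConfig <- function(nClasses = 4L, hetero = TRUE)
  networkConfig(n_classes = nClasses, inner_channels = 6L,
                outer_channels = 4L, stack_thickness = 3L,
                hetero_modal = hetero)

randStack <- function(h = 24L, w = 24L, s = 3L, n = 2L, seed = 1L) {
  set.seed(seed)
  array(rnorm(h * w * s * n), c(h, w, s, n))
}

# a small phantom spec that is quick to rasterize
quickSpec <- function(seed = 1L, voxelSize = 0.8, ...)
  phantomSpec(seed = seed, voxelSize = voxelSize, ...)

writeTempVolume <- function(vol, name = "vol.nii.gz") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeVolume(vol, path)
  path
}

# mean Dice over foreground labels present in the reference
meanForegroundDice <- function(predVol, refVol) {
  pred <- volData(predVol)
  ref <- volData(refVol)
  ids <- sort(unique(ref[ref > 0]))
  mean(vapply(ids, function(id) diceCoefficient(ref == id, pred == id), 0))
}
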