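.defaultViewWeights <- c(axial = 0.4, coronal = 0.4, sagittal = 0.2)

#' Per-plane whole-volume prediction
#'
#' Slices the conformed volume(s) along the network's plane, runs the
#' evaluation-mode forward pass slice-stack by slice-stack, applies the
#' softmax and reassembles a per-class probability volume at native
#' resolution. An absent modality is handled through the fusion module
#' (its weight is zero), never by zero-filled images.
#'
#' @param net an [HMVINN-class].
#' @param vols named list with conformed `t1` and/or `t2`
#'   [BrainVolume-class] entries.
#' @param mode `"t1t2"`, `"t1_only"` or `"t2_only"`.
#' @param lut [LabelLookup-class] giving the class axis (merged table for
#'   sagittal networks).
#' @param batchSize slices per forward pass.
#' @return a [ProbabilityMap-class].
#' @export
predictPlane <- function(net, vols, mode = "t1t2", lut, batchSize = 8L) {
  needT1 <- mode != "t2_only"
  needT2 <- mode != "t1_only"
  if ((needT1 && is.null(vols$t1)) || (needT2 && is.null(vols$t2)))
    .stopf("inputError", "mode %s requires a volume that was not supplied",
           mode)
  use <- vols[c(if (needT1) "t1", if (needT2) "t2")]
  plane <- net@plane
  ax <- .checkPlane(plane)
  stacks <- extractSliceStacks(use, plane, net@cfg$stack_thickness)
  nativeRes <- mean(stacks[[1]]$inPlaneRes)
  ref <- use[[1]]
  d <- dim(volData(ref))
  nC <- net@cfg$n_classes
  ids <- lutTable(lut)$id
  if (nC != length(ids) + 1L)
    .stopf("configError", "network classes do not match the lookup table")

  out <- array(0, c(d, nC))
  n <- length(stacks)
  for (start in seq(1L, n, by = batchSize)) {
    sel <- seq(start, min(start + batchSize - 1L, n))
    xT1 <- if (needT1) .stacksToBatch(stacks, sel, "t1")
    xT2 <- if (needT2) .stacksToBatch(stacks, sel, "t2")
    logits <- forwardLogits(net, xT1, xT2, nativeRes)
    probs <- .softmax4(logits) # (H,W,C,k)
    for (k in seq_along(sel)) {
      pk <- probs[, , , k]
      if (ax == 1L) out[sel[k], , , ] <- pk
      else if (ax == 2L) out[, sel[k], , ] <- pk
      else out[, , sel[k], ] <- pk
    }
  }
  new("ProbabilityMap", data = out, classIds = c(0L, ids),
      voxelSize = voxelSize(ref))
}

#' Expand merged sagittal probabilities to the full label set
#'
#' Each merged class's probability is copied to both lateral descendants
#' (unpaired classes pass through). Per-voxel sums may exceed 1 after the
#' copy; renormalization is deferred to [aggregateViews()] so the fixed
#' 0.4/0.4/0.2 view weighting keeps its meaning.
#'
#' @param p15 [ProbabilityMap-class] on the merged class axis.
#' @param mapping merged-label mapping from [mergeLateralLabels()].
#' @param lut the full [LabelLookup-class].
#' @return [ProbabilityMap-class] on the full class axis.
#' @export
unmergeSagittal <- function(p15, mapping, lut) {
  ids <- lutTable(lut)$id
  mergedIds <- classIds(p15)
  d <- dim(probData(p15))
  out <- array(0, c(d[1:3], length(ids) + 1L))
  out[, , , 1] <- probData(p15)[, , , 1] # background passes through
  for (i in seq_along(ids)) {
    src <- mapping[[as.character(ids[i])]]
    j <- match(src, mergedIds)
    if (is.na(j))
      .stopf("lutError", "merged class %d missing from probability map", src)
    out[, , , i + 1L] <- probData(p15)[, , , j]
  }
  new("ProbabilityMap", data = out, classIds = c(0L, ids),
      voxelSize = voxelSize(p15))
}

#' Weighted view aggregation
#'
#' Elementwise weighted average of the per-plane probability maps
#' (default weights axial 0.4, coronal 0.4, sagittal 0.2), renormalized
#' to a per-voxel simplex. Maps for a subset of planes are aggregated with
#' their weights renormalized.
#'
#' @param maps named list of [ProbabilityMap-class] objects sharing shape
#'   and class axis (`axial`, `coronal`, `sagittal`).
#' @param weights named non-negative weights.
#' @return aggregated [ProbabilityMap-class].
#' @export
aggregateViews <- function(maps, weights = .defaultViewWeights) {
  if (length(maps) == 0L) .stopf("inputError", "no probability maps")
  w <- weights[names(maps)]
  if (any(is.na(w)) || any(w < 0))
    .stopf("parameterError", "invalid view weights")
  dims <- lapply(maps, function(m) dim(probData(m)))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    .stopf("shapeError", "probability maps differ in shape")
  acc <- 0
  for (i in seq_along(maps)) acc <- acc + w[[i]] * probData(maps[[i]])
  s <- rowSums(array(acc, c(prod(dim(acc)[1:3]), dim(acc)[4])), dims = 1)
  s <- array(s, dim(acc)[1:3])
  acc <- acc / as.vector(s) # recycles the voxel-sum across classes
  new("ProbabilityMap", data = acc, classIds = classIds(maps[[1]]),
      voxelSize = voxelSize(maps[[1]]))
}

.argmaxLabels <- function(pmap) {
  d <- dim(probData(pmap))
  m <- matrix(probData(pmap), prod(d[1:3]), d[4])
  cls <- max.col(m, ties.method = "first") # ties -> lowest class index
  array(classIds(pmap)[cls], d[1:3])
}

.volumesTable <- function(labArr, lut, voxmm3) {
  tb <- lutTable(lut)
  cnt <- vapply(tb$id, function(id) sum(labArr == id), 0)
  data.frame(label_id = tb$id, name = tb$name, region = tb$region,
             voxel_count = as.integer(cnt), volume_mm3 = cnt * voxmm3)
}

#' Hetero-modal whole-volume segmentation
#'
#' Conforms the inputs, predicts per supplied plane checkpoint, expands
#' the sagittal map to the full label set, aggregates the views, takes the
#' per-voxel argmax (ties to the lowest class index) and reports plain
#' voxel-count structure volumes (count x voxel volume in mm^3).
#'
#' @param t1,t2 [BrainVolume-class] or `NULL`; at least one required, and
#'   both must share grid and voxel size when given.
#' @param checkpoints named list of [HMVINN-class] networks (or checkpoint
#'   file paths), keyed by plane.
#' @param lut the full [LabelLookup-class].
#' @param mode `"auto"` (use whatever is supplied), `"t1t2"`, `"t1_only"`
#'   or `"t2_only"`.
#' @param viewWeights aggregation weights.
#' @return a [SegmentationResult-class].
#' @export
segment <- function(t1 = NULL, t2 = NULL, checkpoints, lut, mode = "auto",
                    viewWeights = .defaultViewWeights) {
  pr <- .segmentProbs(t1, t2, checkpoints, lut, mode, viewWeights)
  labArr <- .argmaxLabels(pr$pmap)
  ref <- pr$vols[[1]]
  labVol <- new("BrainVolume", data = labArr, voxelSize = voxelSize(ref),
                affine = ref@affine, modality = "LABEL")
  new("SegmentationResult", labelmap = labVol,
      volumes = .volumesTable(labArr, lut, prod(voxelSize(ref))),
      provenance = list(mode = pr$mode, planes = names(checkpoints),
                        view_weights = as.list(pr$weights)))
}

.segmentProbs <- function(t1, t2, checkpoints, lut, mode, viewWeights) {
  if (is.null(t1) && is.null(t2))
    .stopf("inputError", "at least one input modality required")
  if (mode == "auto")
    mode <- if (!is.null(t1) && !is.null(t2)) "t1t2"
            else if (!is.null(t1)) "t1_only" else "t2_only"
  if (mode == "t1t2" && (is.null(t1) || is.null(t2)))
    .stopf("inputError", "mode t1t2 requires both volumes")
  if (mode == "t1_only" && is.null(t1))
    .stopf("inputError", "mode t1_only requires a T1 volume")
  if (mode == "t2_only") {
    if (is.null(t2)) .stopf("inputError", "mode t2_only requires a T2 volume")
    warning("T2-only inference is the lowest-performing input mode; ",
            "interpret results with care", call. = FALSE)
  }
  vols <- list()
  if (!is.null(t1) && mode != "t2_only") vols$t1 <- conform(t1)
  if (!is.null(t2) && mode != "t1_only") vols$t2 <- conform(t2)
  if (length(vols) == 2L) {
    if (!identical(dim(volData(vols$t1)), dim(volData(vols$t2))) ||
        max(abs(voxelSize(vols$t1) - voxelSize(vols$t2))) > 1e-6)
      .stopf("registrationError", "T1 and T2 are not on the same grid")
  }

  nets <- lapply(checkpoints, function(ck)
    if (is.character(ck)) loadCheckpoint(ck, lut = lut) else ck)
  mg <- mergeLateralLabels(lut)
  pmaps <- list()
  for (pl in names(nets)) {
    useLut <- if (pl == "sagittal") mg$merged else lut
    pm <- predictPlane(nets[[pl]], vols, mode, useLut)
    if (pl == "sagittal") pm <- unmergeSagittal(pm, mg$mapping, lut)
    pmaps[[pl]] <- pm
  }
  w <- viewWeights[names(pmaps)]
  agg <- aggregateViews(pmaps, viewWeights)
  list(pmap = agg, vols = vols, mode = mode, weights = w / sum(w))
}

#' Segmentation through a working resolution with soft-label upsampling
#'
#' Runs the network at `workRes` (e.g. the 1.0 mm base resolution),
#' trilinearly up-samples the aggregated soft probability map back to the
#' native grid, renormalizes, and only then takes hard labels — hard label
#' maps are never interpolated.
#'
#' @inheritParams segment
#' @param workRes working voxel size in mm.
#' @return a [SegmentationResult-class].
#' @export
segmentUpsample <- function(t1 = NULL, t2 = NULL, checkpoints, lut,
                            mode = "auto", workRes,
                            viewWeights = .defaultViewWeights) {
  if (workRes <= 0) .stopf("parameterError", "workRes must be positive")
  ct1 <- if (!is.null(t1)) conform(t1)
  ct2 <- if (!is.null(t2)) conform(t2)
  ref <- if (!is.null(ct1)) ct1 else ct2
  dNative <- dim(volData(ref))
  wt1 <- if (!is.null(ct1)) resampleVolume(ct1, workRes)
  wt2 <- if (!is.null(ct2)) resampleVolume(ct2, workRes)
  pr <- .segmentProbs(wt1, wt2, checkpoints, lut, mode, viewWeights)

  p <- probData(pr$pmap)
  for (axn in 1:3) {
    if (dim(p)[axn] == dNative[axn]) next
    p <- .applyAlongAxis(p, .interpMatrix(dim(p)[axn], dNative[axn]), axn)
  }
  s <- array(rowSums(matrix(p, prod(dNative), dim(p)[4])), dNative)
  p <- p / as.vector(s)
  pmap <- new("ProbabilityMap", data = p, classIds = classIds(pr$pmap),
              voxelSize = voxelSize(ref))
  labArr <- .argmaxLabels(pmap)
  labVol <- new("BrainVolume", data = labArr, voxelSize = voxelSize(ref),
                affine = ref@affine, modality = "LABEL")
  new("SegmentationResult", labelmap = labVol,
      volumes = .volumesTable(labArr, lut, prod(voxelSize(ref))),
      provenance = list(mode = pr$mode, planes = names(checkpoints),
                        view_weights = as.list(pr$weights),
                        work_res = workRes))
}
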