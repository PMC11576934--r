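#' @import methods
NULL

#' BrainVolume: a 3D scalar image with voxel geometry
#'
#' The unit of data moved through I/O, conforming, augmentation and
#' inference. Holds the raw 3D array, the voxel edge lengths in mm, the
#' 4x4 voxel-to-world affine, and a modality tag (`"T1"`, `"T2"` or
#' `"LABEL"`). Label volumes carry integer structure codes and are never
#' intensity-rescaled.
#'
#' @slot data 3D numeric array.
#' @slot voxelSize numeric(3), voxel edge lengths in mm (all > 0).
#' @slot affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @slot modality one of `"T1"`, `"T2"`, `"LABEL"`.
#' @exportClass BrainVolume
setClass("BrainVolume",
  representation(data = "array", voxelSize = "numeric",
                 affine = "matrix", modality = "character"))

setValidity("BrainVolume", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive reals")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (!object@modality %in% c("T1", "T2", "LABEL"))
    msg <- c(msg, "modality must be one of T1, T2, LABEL")
  if (object@modality == "LABEL" &&
      any(object@data != round(object@data)))
    msg <- c(msg, "LABEL volumes must contain integer values")
  if (is.null(msg)) TRUE else msg
})

#' LabelLookup: structure lookup table
#'
#' Maps integer label codes to structure names, anatomical region groups,
#' lateral partners and display colors. The shipped default table has 24
#' entries covering the hypothalamic sub-regions (anterior, middle,
#' posterior), the optic structures and adjacent structures; laterally
#' paired entries reference each other through `partner` and differ only
#' by an `L-`/`R-` name prefix.
#'
#' @slot table data.frame with columns `id`, `name`, `region`, `partner`
#'   (NA for midline structures), `r`, `g`, `b`.
#' @exportClass LabelLookup
setClass("LabelLookup", representation(table = "data.frame"))

.lut_regions <- c("hypothalamic-anterior", "hypothalamic-middle",
                  "hypothalamic-posterior", "optic", "others")

setValidity("LabelLookup", function(object) {
  tb <- object@table
  need <- c("id", "name", "region", "partner", "r", "g", "b")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  msg <- NULL
  if (anyDuplicated(tb$id) || any(tb$id == 0) || any(tb$id < 0))
    msg <- c(msg, "label ids must be unique, nonzero and positive")
  if (!all(tb$region %in% .lut_regions))
    msg <- c(msg, "unknown region group")
  for (i in seq_len(nrow(tb))) {
    p <- tb$partner[i]
    if (is.na(p)) next
    j <- match(p, tb$id)
    if (is.na(j))
      msg <- c(msg, sprintf("partner %d of label %d not in table", p, tb$id[i]))
    else {
      if (!identical(tb$partner[j], tb$id[i]))
        msg <- c(msg, sprintf("partner relation asymmetric for label %d", tb$id[i]))
      if (.strip_side(tb$name[i]) != .strip_side(tb$name[j]))
        msg <- c(msg, sprintf("partnered labels %d/%d differ by more than the L-/R- prefix",
                              tb$id[i], tb$id[j]))
    }
  }
  if (is.null(msg)) TRUE else msg
})

.strip_side <- function(x) sub("^[LR]-", "", x)

#' ProbabilityMap: per-class soft prediction volume
#'
#' Soft class probabilities on the conformed voxel grid. The array is
#' stored (X, Y, Z, class); each voxel's class vector lies on the
#' probability simplex.
#'
#' @slot data 4D numeric array (X, Y, Z, n_classes).
#' @slot classIds integer label codes for the class axis (0 = background
#'   first).
#' @slot voxelSize numeric(3), mm.
#' @exportClass ProbabilityMap
setClass("ProbabilityMap",
  representation(data = "array", classIds = "integer", voxelSize = "numeric"))

setValidity("ProbabilityMap", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D (X,Y,Z,class) array")
  if (d[4] != length(object@classIds))
    return("classIds length must match the class axis")
  if (min(object@data) < -1e-8 || max(object@data) > 1 + 1e-8)
    return("probabilities must lie in [0,1]")
  TRUE
})

#' SegmentationResult: hard labels plus structure volumes
#'
#' @slot labelmap a `LABEL` [BrainVolume-class].
#' @slot volumes data.frame (label_id, name, region, voxel_count,
#'   volume_mm3).
#' @slot provenance list: input modes, checkpoint fingerprints, view
#'   weights.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(labelmap = "BrainVolume", volumes = "data.frame",
                 provenance = "list"))

#' MetricsReport: per-structure and aggregated segmentation metrics
#'
#' Rows carry per-label Dice, volume similarity and HD95 (mm); the
#' aggregate table carries unweighted means per region group plus a
#' global mean over structures present in either map.
#'
#' @slot rows data.frame (label_id, name, region, dice, vs, hd95_mm,
#'   present).
#' @slot aggregates data.frame (level, dice, vs, hd95_mm).
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(rows = "data.frame", aggregates = "data.frame"))

#' HMVINN: a hetero-modal, resolution-independent 2D F-CNN
#'
#' One per-plane network: modality-specific competitive dense blocks, the
#' normalized fusion module, a five-block encoder/decoder with bottleneck,
#' and network-integrated resolution-normalization between the native and
#' internal base resolution.
#'
#' @slot cfg list, see [networkConfig()].
#' @slot params named list of parameter arrays.
#' @slot bnStats named list of batch-norm running moments.
#' @slot plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @slot lutHash fingerprint of the lookup table the class axis follows.
#' @slot epochsTrained integer.
#' @exportClass HMVINN
setClass("HMVINN",
  representation(cfg = "list", params = "list", bnStats = "list",
                 plane = "character", lutHash = "character",
                 epochsTrained = "integer"))

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainVolume [%s] %d x %d x %d @ (%.3g, %.3g, %.3g) mm\n",
              object@modality, d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "LabelLookup", function(object) {
  tb <- object@table
  cat(sprintf("LabelLookup with %d labels (%d lateral pairs)\n",
              nrow(tb), sum(!is.na(tb$partner)) / 2L))
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProbabilityMap %d x %d x %d, %d classes\n",
              d[1], d[2], d[3], d[4]))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d labelled structures, %.1f mm3 total\n",
              sum(object@volumes$voxel_count > 0),
              sum(object@volumes$volume_mm3)))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  print(object@aggregates, row.names = FALSE)
})

setMethod("show", "HMVINN", function(object) {
  cat(sprintf(
    "HMVINN (%s plane): %d classes, %d/%d channels, %s parameters, %d epochs\n",
    object@plane, object@cfg$n_classes, object@cfg$inner_channels,
    object@cfg$outer_channels,
    format(countParameters(object), big.mark = ","), object@epochsTrained))
})
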