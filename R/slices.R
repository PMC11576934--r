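.planeAxis <- c(sagittal = 1L, axial = 2L, coronal = 3L)

.checkPlane <- function(plane) {
  if (!plane %in% names(.planeAxis))
    .stopf("parameterError", "plane must be axial, coronal or sagittal")
  .planeAxis[[plane]]
}

# in-plane array axes (row, col) for a slicing plane
.inPlaneAxes <- function(plane) setdiff(1:3, .checkPlane(plane))

#' Extract 2.5D multi-slice stacks from co-registered volumes
#'
#' For every slice index along the plane's axis, gathers `thickness`
#' neighbouring slices (edge-replicated at the borders) for each supplied
#' modality. Stack arrays have shape (S, H, W) with the centre slice at
#' position `(S+1)/2`.
#'
#' @param vols named list of conformed [BrainVolume-class] objects
#'   (e.g. `list(t1 = ..., t2 = ...)`), sharing shape and voxel size.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param thickness odd integer, number of slices per stack.
#' @return list of slice stacks; each has `plane`, `centerIndex`,
#'   `inPlaneRes` and one (S,H,W) array per modality.
#' @export
extractSliceStacks <- function(vols, plane, thickness = 7L) {
  if (!.isOdd(thickness))
    .stopf("parameterError", "stack thickness must be odd")
  ax <- .checkPlane(plane)
  dims <- lapply(vols, function(v) dim(volData(v)))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    .stopf("registrationError", "modalities differ in shape")
  vsz <- lapply(vols, voxelSize)
  if (max(abs(do.call(rbind, vsz) -
              rep(vsz[[1]], each = length(vsz)))) > 1e-6)
    .stopf("registrationError", "modalities differ in voxel size")

  d <- dims[[1]]
  n <- d[ax]
  h <- (thickness - 1L) %/% 2L
  ip <- .inPlaneAxes(plane)
  res <- vsz[[1]][ip]

  # reorder once so the slicing axis is first: (n, H, W)
  arr <- lapply(vols, function(v) aperm(volData(v), c(ax, ip)))

  lapply(seq_len(n), function(i) {
    sel <- .clamp(seq(i - h, i + h), 1L, n)
    stack <- lapply(arr, function(a) a[sel, , , drop = FALSE])
    c(list(plane = plane, centerIndex = i, inPlaneRes = res), stack)
  })
}

#' Reassemble the centre slices of a stack sequence into a volume
#'
#' The inverse of [extractSliceStacks()] for one modality: taking the
#' centre slice of every stack reproduces the conformed volume exactly.
#'
#' @param stacks list returned by [extractSliceStacks()].
#' @param what name of the modality entry to reassemble.
#' @return 3D array in canonical axis order.
#' @export
reassembleCenterSlices <- function(stacks, what = "t1") {
  plane <- stacks[[1]]$plane
  ax <- .checkPlane(plane)
  ip <- .inPlaneAxes(plane)
  s <- dim(stacks[[1]][[what]])[1]
  centre <- (s + 1L) %/% 2L
  sl <- lapply(stacks, function(st) st[[what]][centre, , ])
  a <- array(unlist(sl), dim = c(dim(stacks[[1]][[what]])[2:3], length(sl)))
  a <- aperm(a, c(3, 1, 2)) # (n, H, W)
  aperm(a, order(c(ax, ip)))
}
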