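#' Construct a BrainVolume
#'
#' @param data 3D numeric array.
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to the
#'   canonical axis-aligned affine centred on the field of view.
#' @param modality `"T1"`, `"T2"` or `"LABEL"`.
#' @return a [BrainVolume-class].
#' @export
BrainVolume <- function(data, voxelSize, affine = NULL, modality = "T1") {
  voxelSize <- as.numeric(voxelSize)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (is.null(affine)) affine <- canonicalAffine(dim(data), voxelSize)
  new("BrainVolume", data = data, voxelSize = voxelSize, affine = affine,
      modality = modality)
}

# Canonical voxel-to-world affine: array axis 1 runs to the left (-X),
# axis 2 inferior (-Z), axis 3 anterior (+Y); volume centred at the
# world origin. This is the LIA-like convention all conformed volumes use,
# giving fixed plane semantics: sagittal = axis 1, axial = axis 2,
# coronal = axis 3.
canonicalAffine <- function(dims, voxelSize) {
  R <- cbind(c(-voxelSize[1], 0, 0),
             c(0, 0, -voxelSize[2]),
             c(0, voxelSize[3], 0))
  centre <- (dims - 1) / 2
  rbind(cbind(R, -R %*% centre), c(0, 0, 0, 1))
}

# target (world axis, sign) for each canonical array axis
.canonicalTargets <- matrix(c(1, -1, 3, -1, 2, +1), nrow = 2)

#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti. Voxel sizes come from the header pixdim;
#' the world affine is preserved (sform preferred over qform when both are
#' valid).
#'
#' @param path NIfTI-1/NIfTI-2 file (.nii or .nii.gz).
#' @param modality `"T1"`, `"T2"` or `"LABEL"`.
#' @return a [BrainVolume-class].
#' @export
readVolume <- function(path, modality = "T1") {
  if (!file.exists(path)) .stopf("ioError", "file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    .stopf("shapeError", "expected a 3D image, got %d dimensions", length(d))
  vs <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vs)) || any(vs <= 0))
    .stopf("headerError", "non-positive voxel size in header")
  aff <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                   code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  x <- array(as.numeric(img), dim = d)
  if (modality == "LABEL") x <- round(x)
  BrainVolume(x, vs, aff, modality)
}

#' @rdname readVolume
#' @param vol a [BrainVolume-class].
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(volData(vol))
  RNifti::pixdim(img) <- voxelSize(vol)
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::qform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Conform a volume to the canonical orientation and intensity scale
#'
#' Reorients the array (axis permutation and flips only, no resampling) so
#' that the canonical axis convention holds: axis 1 left, axis 2 inferior,
#' axis 3 anterior. Slicing planes are then deterministic: sagittal along
#' axis 1, axial along axis 2, coronal along axis 3. Intensity volumes are
#' rescaled to `[0, 1]` by robust min-max (0.1/99.9 percentiles); LABEL
#' volumes are never rescaled. A volume already canonical with intensities
#' in `[0, 1]` is returned unchanged, making conform idempotent.
#'
#' @param vol a [BrainVolume-class].
#' @return conformed [BrainVolume-class].
#' @export
conform <- function(vol) {
  M <- vol@affine[1:3, 1:3]
  if (abs(det(M)) < 1e-12)
    .stopf("orientationError", "singular affine")
  cols <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  # refuse sheared grids: normalized direction cosines must be orthogonal
  ip <- abs(crossprod(cols)) - diag(3)
  if (max(ip) > 1e-3)
    .stopf("orientationError", "affine has shear > 1e-3")

  domAxis <- apply(abs(cols), 2, which.max)
  if (anyDuplicated(domAxis))
    .stopf("orientationError", "cannot determine axis permutation")
  domSign <- sign(cols[cbind(domAxis, 1:3)])

  perm <- integer(3)
  flip <- logical(3)
  for (i in 1:3) {
    j <- which(domAxis == .canonicalTargets[1, i])
    perm[i] <- j
    flip[i] <- domSign[j] != .canonicalTargets[2, i]
  }

  x <- volData(vol)
  already <- identical(perm, 1:3) && !any(flip)
  if (!already) {
    x <- aperm(x, perm)
    if (flip[1]) x <- x[dim(x)[1]:1, , , drop = FALSE]
    if (flip[2]) x <- x[, dim(x)[2]:1, , drop = FALSE]
    if (flip[3]) x <- x[, , dim(x)[3]:1, drop = FALSE]
  }

  # new affine: old voxel index as a function of the new one
  Tm <- matrix(0, 4, 4); Tm[4, 4] <- 1
  dOld <- dim(volData(vol))
  for (i in 1:3) {
    Tm[perm[i], i] <- if (flip[i]) -1 else 1
    if (flip[i]) Tm[perm[i], 4] <- dOld[perm[i]] - 1
  }
  aff <- vol@affine %*% Tm
  vs <- sqrt(colSums(M^2))[perm]

  if (vol@modality != "LABEL") {
    if (!(min(x) >= 0 && max(x) <= 1)) x <- .robustRescale(x)
  }
  new("BrainVolume", data = x, voxelSize = vs, affine = aff,
      modality = vol@modality)
}

# 1D interpolation matrix (linear, half-pixel-centre convention) mapping a
# length-nIn axis onto nOut samples. Rows sum to 1.
.interpMatrix <- function(nIn, nOut, nearest = FALSE) {
  ratio <- nIn / nOut
  src <- (seq_len(nOut) - 0.5) * ratio - 0.5
  if (nearest) {
    j <- .clamp(round(src), 0, nIn - 1)
    A <- matrix(0, nOut, nIn)
    A[cbind(seq_len(nOut), j + 1)] <- 1
    return(A)
  }
  src <- .clamp(src, 0, nIn - 1)
  j0 <- pmin(floor(src), nIn - 1)
  w1 <- src - j0
  j1 <- pmin(j0 + 1, nIn - 1)
  A <- matrix(0, nOut, nIn)
  A[cbind(seq_len(nOut), j0 + 1)] <- A[cbind(seq_len(nOut), j0 + 1)] + (1 - w1)
  A[cbind(seq_len(nOut), j1 + 1)] <- A[cbind(seq_len(nOut), j1 + 1)] + w1
  A
}

# apply interpolation matrix along one axis of a 3D (or 4D) array
.applyAlongAxis <- function(x, A, axis) {
  d <- dim(x)
  p <- seq_along(d)
  p[c(1, axis)] <- p[c(axis, 1)]
  xp <- aperm(x, p)
  dp <- dim(xp)
  m <- A %*% matrix(xp, dp[1], prod(dp[-1]))
  dp[1] <- nrow(A)
  aperm(array(m, dp), p)
}

#' Resample a volume to a new voxel size
#'
#' Trilinear for intensity volumes, nearest-neighbour for labels;
#' implemented as separable 1D interpolations with the half-pixel-centre
#' convention. The grid size becomes `round(dim * old/new)` per axis.
#'
#' @param vol a [BrainVolume-class].
#' @param newVoxelSize numeric(1 or 3), mm.
#' @return resampled [BrainVolume-class].
#' @export
resampleVolume <- function(vol, newVoxelSize) {
  newVoxelSize <- as.numeric(newVoxelSize)
  if (length(newVoxelSize) == 1L) newVoxelSize <- rep(newVoxelSize, 3L)
  if (any(newVoxelSize <= 0)) .stopf("parameterError", "voxel size must be positive")
  d <- dim(volData(vol))
  nd <- pmax(1L, as.integer(round(d * voxelSize(vol) / newVoxelSize)))
  nearest <- modality(vol) == "LABEL"
  x <- volData(vol)
  for (ax in 1:3) {
    if (nd[ax] == d[ax]) next
    x <- .applyAlongAxis(x, .interpMatrix(d[ax], nd[ax], nearest), ax)
  }
  R <- vol@affine[1:3, 1:3]
  Rn <- sweep(R, 2, d / nd, "*")
  offset <- R %*% (0.5 * d / nd - 0.5)
  affn <- vol@affine
  affn[1:3, 1:3] <- Rn
  affn[1:3, 4] <- vol@affine[1:3, 4] + offset
  new("BrainVolume", data = if (nearest) round(x) else x,
      voxelSize = voxelSize(vol) * d / nd, affine = affn,
      modality = modality(vol))
}
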