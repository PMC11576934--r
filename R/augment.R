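# Training-time data augmentation: random affine, multiplicative bias
# field, external (acquisition-level) scale changes, and per-example
# modality dropout.

# trilinear sampling of a 3D array at fractional voxel coordinates
# (3 x n, 1-based), clamped to the grid (edge-value fill)
.sampleTrilinear <- function(arr, co) {
  d <- dim(arr)
  co[1, ] <- .clamp(co[1, ], 1, d[1])
  co[2, ] <- .clamp(co[2, ], 1, d[2])
  co[3, ] <- .clamp(co[3, ], 1, d[3])
  f <- floor(co)
  f[1, ] <- pmin(f[1, ], d[1] - 1); f[2, ] <- pmin(f[2, ], d[2] - 1)
  f[3, ] <- pmin(f[3, ], d[3] - 1)
  w <- co - f
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[1, ] else 1 - w[1, ]) *
          (if (dy) w[2, ] else 1 - w[2, ]) *
          (if (dz) w[3, ] else 1 - w[3, ])
    out <- out + wt * arr[cbind(f[1, ] + dx, f[2, ] + dy, f[3, ] + dz)]
  }
  out
}

.sampleNearest <- function(arr, co) {
  d <- dim(arr)
  i <- round(co)
  i[1, ] <- .clamp(i[1, ], 1, d[1]); i[2, ] <- .clamp(i[2, ], 1, d[2])
  i[3, ] <- .clamp(i[3, ], 1, d[3])
  arr[cbind(i[1, ], i[2, ], i[3, ])]
}

.rotationMatrix <- function(degXYZ) {
  r <- degXYZ * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1]); cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Random affine augmentation of co-registered volumes
#'
#' Samples one rigid-plus-scale transform (translation in mm, rotation in
#' degrees about each axis, one uniform scale factor) and applies it
#' identically to every supplied volume: trilinear interpolation for
#' intensity volumes, nearest-neighbour for labels. Out-of-field samples
#' take the nearest edge value.
#'
#' @param vols named list of [BrainVolume-class] (images and/or a label
#'   volume).
#' @param translationMm length-2 range in mm.
#' @param rotationDeg length-2 range in degrees.
#' @param scaleRange length-2 uniform scaling range.
#' @param seed integer seed; the same seed reproduces the same transform.
#' @return list of transformed volumes.
#' @export
augmentAffine <- function(vols, translationMm = c(-15, 15),
                          rotationDeg = c(-10, 10),
                          scaleRange = c(0.85, 1.15), seed = 1L) {
  pars <- .withSeed(.deriveSeed(seed, "affine"), list(
    t = runif(3, translationMm[1], translationMm[2]),
    r = runif(3, rotationDeg[1], rotationDeg[2]),
    s = runif(1, scaleRange[1], scaleRange[2])))
  R <- .rotationMatrix(pars$r) * pars$s
  Rinv <- solve(R)
  lapply(vols, function(v) {
    d <- dim(volData(v))
    vs <- voxelSize(v)
    g <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
    centre <- (d + 1) / 2
    mm <- t((t(g) - centre) * vs) # voxel -> centred mm
    src <- Rinv %*% (t(mm) - pars$t)
    srcVox <- src / vs + centre
    vals <- if (modality(v) == "LABEL") .sampleNearest(volData(v), srcVox)
            else .sampleTrilinear(volData(v), srcVox)
    new("BrainVolume", data = array(vals, d), voxelSize = vs,
        affine = v@affine, modality = modality(v))
  })
}

#' Random multiplicative bias field
#'
#' Multiplies an intensity volume by `exp(P(x))`, `P` an order-3
#' polynomial in the normalized coordinates with coefficients drawn
#' uniformly from `coeffRange`; the field is strictly positive and labels
#' are never touched.
#'
#' @param vol an intensity [BrainVolume-class].
#' @param coeffRange coefficient range (default the training range
#'   `c(-0.5, 0.5)`).
#' @param seed integer seed.
#' @param order polynomial order.
#' @return biased [BrainVolume-class].
#' @export
augmentBiasField <- function(vol, coeffRange = c(-0.5, 0.5), seed = 1L,
                             order = 3L) {
  if (modality(vol) == "LABEL")
    .stopf("modalityError", "bias field applies to intensity volumes only")
  field <- .biasField(dim(volData(vol)), coeffRange, seed, order)
  new("BrainVolume", data = volData(vol) * field, voxelSize = voxelSize(vol),
      affine = vol@affine, modality = modality(vol))
}

.biasField <- function(d, coeffRange, seed, order = 3L) {
  degs <- as.matrix(expand.grid(i = 0:order, j = 0:order, k = 0:order))
  degs <- degs[rowSums(degs) <= order, , drop = FALSE]
  coef <- .withSeed(.deriveSeed(seed, "bias"),
                    runif(nrow(degs), coeffRange[1], coeffRange[2]))
  ax <- lapply(d, function(n) if (n > 1) seq(-1, 1, length.out = n) else 0)
  P <- array(0, d)
  for (r in seq_len(nrow(degs))) {
    if (coef[r] == 0) next
    P <- P + coef[r] * outer(outer(ax[[1]]^degs[r, 1], ax[[2]]^degs[r, 2]),
                             ax[[3]]^degs[r, 3])
  }
  exp(P)
}

#' External scale augmentation
#'
#' Resamples co-registered volumes to a voxel size drawn uniformly from
#' `resRange`, updating the voxel-size metadata: the example is presented
#' to the network as if acquired at another resolution. Labels are
#' resampled nearest-neighbour and keep their original label set.
#'
#' @param vols named list of [BrainVolume-class].
#' @param resRange voxel-size range in mm.
#' @param seed integer seed.
#' @return list of resampled volumes.
#' @export
externalScaleAugment <- function(vols, resRange = c(0.7, 1.1), seed = 1L) {
  if (any(resRange <= 0)) .stopf("parameterError", "resolutions must be > 0")
  r <- .withSeed(.deriveSeed(seed, "exsa"),
                 runif(1, resRange[1], resRange[2]))
  lapply(vols, resampleVolume, newVoxelSize = r)
}

#' Sample the modality mode for a training example
#'
#' Modality dropout: before the warm-up epoch every example sees both
#' modalities; afterwards the three input combinations (`t1t2`,
#' `t1_only`, `t2_only`) are drawn uniformly per example.
#'
#' @param epoch 1-based epoch number.
#' @param n number of draws.
#' @param startEpoch first epoch at which dropout is active (default 11,
#'   i.e. only after 10 warm-up epochs).
#' @return character vector of modes.
#' @export
sampleModalityMode <- function(epoch, n = 1L, startEpoch = 11L) {
  if (epoch < startEpoch) return(rep("t1t2", n))
  c("t1t2", "t1_only", "t2_only")[sample.int(3L, n, replace = TRUE)]
}
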