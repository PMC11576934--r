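# Synthetic two-contrast brain phantoms. The scene is defined
# continuously in mm (ellipsoids and capsule-shaped tubes with soft
# partial-volume edges), so the same scene can be rasterized at any voxel
# size and per-structure physical volumes agree across resolutions by
# construction. The T1-like and T2-like channels share geometry but use
# partially inverted contrast (ventricle dark in T1, bright in T2), the
# property the hetero-modal fusion is designed to exploit.

# Scene sizing: at 0.8 mm voxels a structure's attainable Dice is limited
# by its surface-to-volume ratio times the boundary localization error, so
# every structure is kept at >= 2 voxels of radius and given channel
# contrasts several times the noise floor — ground truth must be
# recoverable from the images for segmentation experiments to be
# meaningful (an intensity-oracle check in the tests enforces this).
.toyStructures <- function() {
  list(
    list(id = 1L, type = "ellipsoid", center = c(0, 0.5, 0),
         radii = c(2.4, 5.2, 3.6)),
    list(id = 2L, type = "ellipsoid", center = c(5.8, -2.0, 1.5),
         radii = c(3.2, 3.2, 3.2)),
    list(id = 3L, type = "ellipsoid", center = c(-5.8, -2.0, 1.5),
         radii = c(3.2, 3.2, 3.2)),
    list(id = 4L, type = "tube", p0 = c(4.8, 4.0, -8.5),
         p1 = c(4.8, 4.0, 8.5), radius = 1.8),
    list(id = 5L, type = "tube", p0 = c(-4.8, 4.0, -8.5),
         p1 = c(-4.8, 4.0, 8.5), radius = 1.8),
    list(id = 6L, type = "tube", p0 = c(-5.5, -6.0, -4.5),
         p1 = c(5.5, -6.0, -4.5), radius = 1.6))
}

.toyContrast <- function() {
  list(background = c(t1 = 0.55, t2 = 0.35),
       t1 = c("1" = 0.12, "2" = 0.85, "3" = 0.85, "4" = 0.95, "5" = 0.95,
              "6" = 0.28),
       t2 = c("1" = 0.95, "2" = 0.60, "3" = 0.60, "4" = 0.15, "5" = 0.15,
              "6" = 0.58))
}

#' Phantom specification
#'
#' Defines the continuous scene (structures in mm, mirrored lateral
#' pairs), the per-channel contrast tables, the acquisition (voxel size,
#' additive Gaussian noise, optional smooth multiplicative bias field)
#' and the seed. The defaults give the 6-label toy scene used for
#' desk-scale training: a midline ventricle with inverted contrast
#' between channels, a lateral pair of nucleus-like spheres, a pair of
#' optic-tract-like tubes and a midline commissure-like rod in a 25.6 mm
#' field of view.
#'
#' @param seed integer.
#' @param fovMm isotropic field of view in mm.
#' @param voxelSize isotropic voxel size in mm.
#' @param lut a [LabelLookup-class] matching the structure ids.
#' @param structures list of structure definitions (`ellipsoid` with
#'   `center`/`radii`, `tube` with `p0`/`p1`/`radius`), ordered by
#'   precedence (first wins where shapes overlap).
#' @param contrast list with `background` and per-channel mean-intensity
#'   tables.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param bias apply a smooth multiplicative bias field.
#' @param biasCoeff bias-field polynomial coefficient half-range; the
#'   default 0.05 yields fields mostly within +-10% across the field of
#'   view (worst-case corners around +-40%), the inhomogeneity scale of
#'   uncorrected research MRI.
#' @param edgeMm width of the soft partial-volume edge.
#' @return validated spec list.
#' @export
phantomSpec <- function(seed = 1L, fovMm = 25.6, voxelSize = 0.8,
                        lut = toyLUT(), structures = .toyStructures(),
                        contrast = .toyContrast(), noiseSd = 0.04,
                        bias = TRUE, biasCoeff = 0.05, edgeMm = 0.8) {
  if (voxelSize <= 0 || fovMm <= 0)
    .stopf("specError", "fov and voxel size must be positive")
  half <- fovMm / 2
  for (s in structures) {
    ext <- switch(s$type,
      ellipsoid = abs(s$center) + s$radii,
      tube = pmax(abs(s$p0), abs(s$p1)) + s$radius,
      .stopf("specError", "unknown structure type %s", s$type))
    if (any(ext > half))
      .stopf("specError", "structure %d extends outside the field of view",
             s$id)
    if (!s$id %in% lutTable(lut)$id)
      .stopf("specError", "structure id %d not in the lookup table", s$id)
  }
  list(seed = as.integer(seed), fovMm = fovMm, voxelSize = voxelSize,
       lut = lut, structures = structures, contrast = contrast,
       noiseSd = noiseSd, bias = isTRUE(bias), biasCoeff = biasCoeff,
       edgeMm = edgeMm)
}

# soft membership in [0,1]: 0.5 exactly on the continuous surface,
# reaching 0/1 over edgeMm
.membership <- function(s, X, edgeMm) {
  if (s$type == "ellipsoid") {
    rho <- sqrt(((X[, 1] - s$center[1]) / s$radii[1])^2 +
                ((X[, 2] - s$center[2]) / s$radii[2])^2 +
                ((X[, 3] - s$center[3]) / s$radii[3])^2)
    scale <- mean(s$radii)
  } else {
    v <- s$p1 - s$p0
    len2 <- sum(v^2)
    t <- .clamp(((X[, 1] - s$p0[1]) * v[1] + (X[, 2] - s$p0[2]) * v[2] +
                 (X[, 3] - s$p0[3]) * v[3]) / len2, 0, 1)
    dx <- X[, 1] - (s$p0[1] + t * v[1])
    dy <- X[, 2] - (s$p0[2] + t * v[2])
    dz <- X[, 3] - (s$p0[3] + t * v[3])
    rho <- sqrt(dx^2 + dy^2 + dz^2) / s$radius
    scale <- s$radius
  }
  .clamp(0.5 + (1 - rho) * scale / edgeMm, 0, 1)
}

#' Generate a phantom triplet
#'
#' Rasterizes the continuous scene onto the voxel grid: the label map is
#' filled by structure precedence (membership above one half), both
#' channels blend the structure means over the soft edge (an analytic
#' partial-volume profile, which also makes the two channels negatively
#' correlated inside contrast-inverted structures), then additive noise
#' and the optional bias field are applied. Deterministic given the spec
#' seed.
#'
#' @param spec a [phantomSpec()].
#' @return list with `t1`, `t2` and `labels` [BrainVolume-class] objects
#'   on the canonical grid.
#' @export
generatePhantom <- function(spec) {
  n <- max(1L, as.integer(round(spec$fovMm / spec$voxelSize)))
  d <- c(n, n, n)
  ax <- (seq_len(n) - 0.5) * spec$voxelSize - spec$fovMm / 2
  X <- as.matrix(expand.grid(x = ax, y = ax, z = ax))

  lab <- integer(nrow(X))
  t1 <- rep(spec$contrast$background[["t1"]], nrow(X))
  t2 <- rep(spec$contrast$background[["t2"]], nrow(X))
  for (s in rev(spec$structures)) { # earlier entries take precedence
    phi <- .membership(s, X, spec$edgeMm)
    inside <- phi >= 0.5
    lab[inside] <- s$id
    key <- as.character(s$id)
    t1 <- t1 * (1 - phi) + spec$contrast$t1[[key]] * phi
    t2 <- t2 * (1 - phi) + spec$contrast$t2[[key]] * phi
  }
  if (spec$noiseSd > 0) {
    t1 <- t1 + .withSeed(.deriveSeed(spec$seed, "noise.t1"),
                         rnorm(length(t1), 0, spec$noiseSd))
    t2 <- t2 + .withSeed(.deriveSeed(spec$seed, "noise.t2"),
                         rnorm(length(t2), 0, spec$noiseSd))
  }
  t1 <- array(t1, d); t2 <- array(t2, d)
  if (spec$bias) {
    t1 <- t1 * .biasField(d, c(-spec$biasCoeff, spec$biasCoeff),
                          .deriveSeed(spec$seed, "fbias.t1"))
    t2 <- t2 * .biasField(d, c(-spec$biasCoeff, spec$biasCoeff),
                          .deriveSeed(spec$seed, "fbias.t2"))
  }
  list(t1 = BrainVolume(t1, spec$voxelSize, modality = "T1"),
       t2 = BrainVolume(t2, spec$voxelSize, modality = "T2"),
       labels = BrainVolume(array(lab, d), spec$voxelSize,
                            modality = "LABEL"))
}

#' Rasterize one scene at two voxel sizes
#'
#' Both triplets come from the identical continuous scene (same seed), so
#' per-structure physical volumes agree across resolutions within
#' rasterization tolerance — the basis of the cross-resolution
#' consistency tests.
#'
#' @param spec a [phantomSpec()].
#' @param resA,resB distinct voxel sizes in mm.
#' @return list with elements `a` and `b`, each a phantom triplet.
#' @export
generateMultiresPair <- function(spec, resA, resB) {
  if (resA == resB) .stopf("specError", "resolutions must differ")
  sa <- spec; sa$voxelSize <- resA
  sb <- spec; sb$voxelSize <- resB
  list(a = generatePhantom(sa), b = generatePhantom(sb))
}

#' Generate a phantom dataset with jittered scenes
#'
#' Draws `n` phantoms whose structure centres and sizes are jittered
#' (seeded; lateral pairs are jittered jointly and mirrored, preserving
#' symmetry), conforms them, and splits deterministically into training
#' and validation collections. The returned label histogram of the
#' training split feeds [medianFrequencyWeights()].
#'
#' @param n number of phantoms.
#' @param baseSpec a [phantomSpec()].
#' @param seed dataset seed.
#' @param valFraction fraction held out for validation (last phantoms).
#' @param centerJitterMm uniform centre jitter half-range (mm).
#' @param radiusJitter multiplicative radius jitter half-range.
#' @return list with `train`, `validation`, `histogram`, `specs`.
#' @export
makeDataset <- function(n, baseSpec = phantomSpec(), seed = 1L,
                        valFraction = 1 / 3, centerJitterMm = 1.2,
                        radiusJitter = 0.1) {
  if (n < 1L) .stopf("inputError", "need n >= 1")
  tb <- lutTable(baseSpec$lut)
  samples <- vector("list", n)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- baseSpec
    sp$seed <- .deriveSeed(seed, sprintf("phantom.%d", i))
    sp$structures <- .withSeed(.deriveSeed(seed, sprintf("jitter.%d", i)),
      .jitterStructures(baseSpec$structures, tb, centerJitterMm,
                        radiusJitter))
    specs[[i]] <- sp
    ph <- generatePhantom(sp)
    samples[[i]] <- list(t1 = conform(ph$t1), t2 = conform(ph$t2),
                         labels = conform(ph$labels))
  }
  nVal <- min(n - 1L, round(n * valFraction))
  if (n == 1L) nVal <- 0L
  trainIdx <- seq_len(n - nVal)
  valIdx <- setdiff(seq_len(n), trainIdx)
  train <- samples[trainIdx]
  list(train = train, validation = samples[valIdx],
       histogram = datasetLabelHistogram(train, baseSpec$lut),
       specs = specs)
}

.jitterStructures <- function(structures, tb, centerJitterMm, radiusJitter) {
  ids <- vapply(structures, function(s) s$id, 1L)
  done <- logical(length(structures))
  out <- structures
  mirror1 <- function(v) c(-v[1], v[2], v[3])
  for (i in seq_along(structures)) {
    if (done[i]) next
    s <- structures[[i]]
    dc <- runif(3, -centerJitterMm, centerJitterMm)
    dr <- runif(1, 1 - radiusJitter, 1 + radiusJitter)
    s2 <- s
    if (s$type == "ellipsoid") {
      s2$center <- s$center + dc
      s2$radii <- s$radii * dr
    } else {
      s2$p0 <- s$p0 + dc; s2$p1 <- s$p1 + dc
      s2$radius <- s$radius * dr
    }
    out[[i]] <- s2
    done[i] <- TRUE
    partner <- tb$partner[match(s$id, tb$id)]
    if (!is.na(partner)) {
      j <- match(partner, ids)
      if (!is.na(j) && !done[j]) { # mirrored copy across the midline
        sm <- out[[j]]
        if (s$type == "ellipsoid") {
          sm$center <- mirror1(s2$center)
          sm$radii <- s2$radii
        } else {
          sm$p0 <- mirror1(s2$p0); sm$p1 <- mirror1(s2$p1)
          sm$radius <- s2$radius
        }
        out[[j]] <- sm
        done[j] <- TRUE
      }
    }
  }
  out
}
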