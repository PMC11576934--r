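lutToy <- toyLUT()

smallTrainedNet <- function(plane = "coronal") {
  # untrained but frozen random weights are enough for contract tests
  cfg <- networkConfig(n_classes = nClassesFor(lutToy, plane),
                       inner_channels = 8, outer_channels = 4)
  buildFCNN(cfg, plane, if (plane == "sagittal")
    mergeLateralLabels(lutToy)$merged else lutToy, seed = 12)
}

test_that("predictPlane yields per-voxel simplex maps, deterministically", {
  ph <- generatePhantom(quickSpec(seed = 3))
  vols <- list(t1 = conform(ph$t1), t2 = conform(ph$t2))
  net <- smallTrainedNet()
  pm <- predictPlane(net, vols, "t1t2", lutToy)
  d <- dim(probData(pm))
  expect_equal(d, c(32L, 32L, 32L, 7L))
  sums <- apply(probData(pm), 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  pm2 <- predictPlane(net, vols, "t1t2", lutToy)
  expect_identical(probData(pm), probData(pm2))
  expect_error(predictPlane(net, list(t1 = vols$t1), "t1t2", lutToy),
               class = "inputError")
})

test_that("T1-only prediction equals zeroed T2 fusion weight", {
  ph <- generatePhantom(quickSpec(seed = 5))
  vols <- list(t1 = conform(ph$t1), t2 = conform(ph$t2))
  net <- smallTrainedNet()
  netZ <- net; netZ@params$fuse.w2 <- 0
  expect_identical(probData(predictPlane(net, list(t1 = vols$t1), "t1_only",
                                         lutToy)),
                   probData(predictPlane(netZ, vols, "t1t2", lutToy)))
})

test_that("sagittal unmerge copies probabilities to both partners", {
  mg <- mergeLateralLabels(lutToy)
  mids <- lutTable(mg$merged)$id
  d <- c(2, 2, 2)
  # one-hot style map on the merged axis
  p <- array(0, c(d, length(mids) + 1))
  p[, , , 1] <- 0.4
  j <- match(2L, mids) + 1L # merged nucleus class
  p[, , , j] <- 0.6
  p15 <- new("ProbabilityMap", data = p, classIds = c(0L, mids),
             voxelSize = rep(1, 3))
  p24 <- unmergeSagittal(p15, mg$mapping, lutToy)
  ids <- classIds(p24)
  expect_equal(probData(p24)[1, 1, 1, match(2L, ids)], 0.6)
  expect_equal(probData(p24)[1, 1, 1, match(3L, ids)], 0.6)

  # unmerge(merge(one-hot)) restores support on both partners, all labels
  for (id in lutTable(lutToy)$id) {
    ph <- array(0, c(d, length(mids) + 1))
    ph[, , , match(mg$mapping[[as.character(id)]], mids) + 1L] <- 1
    pmh <- new("ProbabilityMap", data = ph, classIds = c(0L, mids),
               voxelSize = rep(1, 3))
    out <- unmergeSagittal(pmh, mg$mapping, lutToy)
    expect_equal(probData(out)[1, 1, 1, match(id, classIds(out))], 1)
    partner <- lutTable(lutToy)$partner[match(id, lutTable(lutToy)$id)]
    if (!is.na(partner))
      expect_equal(probData(out)[1, 1, 1, match(partner, classIds(out))], 1)
  }
})

test_that("view aggregation averages, renormalizes and respects weights", {
  d <- c(3, 3, 3)
  mk <- function(cls, p = 1) {
    a <- array((1 - p) / 2, c(d, 3))
    a[, , , cls] <- p
    new("ProbabilityMap", data = a, classIds = c(0L, 1L, 2L),
        voxelSize = rep(1, 3))
  }
  same <- aggregateViews(list(axial = mk(2), coronal = mk(2),
                              sagittal = mk(2)))
  expect_equal(probData(same), probData(mk(2)), tolerance = 1e-12)

  # axial+coronal say class A (0.8 weight), sagittal says class B (0.2)
  agg <- aggregateViews(list(axial = mk(2), coronal = mk(2),
                             sagittal = mk(3)))
  expect_equal(which.max(agg@data[1, 1, 1, ]), 2L)

  only <- aggregateViews(list(axial = mk(3)), weights = c(axial = 1))
  expect_equal(probData(only), probData(mk(3)), tolerance = 1e-12)
  sums <- apply(probData(agg), 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
})

test_that("segment produces voxel-count volumes and stable argmax ties", {
  ph <- generatePhantom(quickSpec(seed = 7))
  cks <- list(coronal = smallTrainedNet())
  res <- segment(ph$t1, ph$t2, cks, lutToy)
  expect_equal(dim(volData(labelMap(res))), c(32L, 32L, 32L))
  tb <- structureVolumes(res)
  expect_equal(tb$volume_mm3, tb$voxel_count * 0.8^3, tolerance = 1e-12)
  # 100 voxels at 0.8mm isotropic would give 51.2 mm3
  expect_equal(100 * prod(voxelSize(labelMap(res))), 51.2, tolerance = 1e-9)
  expect_error(segment(NULL, NULL, cks, lutToy), class = "inputError")
  expect_warning(segment(NULL, ph$t2, cks, lutToy, mode = "t2_only"),
                 "lowest-performing")
})

test_that("argmax ties break to the lowest class index", {
  p <- array(0.5, c(1, 1, 1, 2))
  pm <- new("ProbabilityMap", data = p, classIds = c(0L, 1L),
            voxelSize = rep(1, 3))
  expect_equal(hyposeg:::.argmaxLabels(pm)[1, 1, 1], 0L)
})

test_that("upsampled soft-label segmentation matches segment at native res", {
  ph <- generatePhantom(quickSpec(seed = 8))
  cks <- list(coronal = smallTrainedNet())
  a <- segment(ph$t1, ph$t2, cks, lutToy)
  b <- segmentUpsample(ph$t1, ph$t2, cks, lutToy, workRes = 0.8)
  expect_identical(volData(labelMap(a)), volData(labelMap(b)))
})

test_that("probability sums survive trilinear upsampling", {
  ph <- generatePhantom(quickSpec(seed = 9))
  cks <- list(coronal = smallTrainedNet())
  res <- segmentUpsample(ph$t1, ph$t2, cks, lutToy, workRes = 1.0)
  expect_equal(dim(volData(labelMap(res))), c(32L, 32L, 32L))
  # interior of large one-hot regions is stable under upsample+argmax
  p <- array(0, c(4, 4, 4, 2)); p[, , , 1] <- 1
  p[3:4, , , 1] <- 0; p[3:4, , , 2] <- 1
  up <- p
  for (ax in 1:3) up <- hyposeg:::.applyAlongAxis(
    up, hyposeg:::.interpMatrix(4L, 8L), ax)
  lab <- apply(up, 1:3, which.max)
  expect_true(all(lab[1:3, , ] == 1)) # deep interior of region A
  expect_true(all(lab[7:8, , ] == 2)) # deep interior of region B
  s <- apply(up, 1:3, sum)
  expect_lt(max(abs(s - 1)), 1e-5)
})
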