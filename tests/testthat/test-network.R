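test_that("fusion reproduces the normalized weighted sum", {
  f1 <- array(2, c(4, 4, 2, 1))
  f2 <- array(4, c(4, 4, 2, 1))
  expect_equal(fuseFeatureMaps(f1, f2, 0.5, 0.5), array(3, c(4, 4, 2, 1)))
  # independent scalar evaluation: 0.75*1 + 0.25*5 = 2
  expect_equal(fuseFeatureMaps(array(1, c(2, 2, 1, 1)),
                               array(5, c(2, 2, 1, 1)), 0.3, 0.1),
               array(2, c(2, 2, 1, 1)))
})

test_that("fusion with an absent modality is an exact passthrough", {
  set.seed(4)
  f1 <- array(rnorm(32), c(4, 4, 2, 1))
  expect_identical(fuseFeatureMaps(f1, NULL, 0.5, 0), f1)
  expect_identical(fuseFeatureMaps(NULL, f1, 0, 0.5), f1)
})

test_that("fusion error conditions", {
  f <- array(0, c(2, 2, 1, 1))
  expect_error(fuseFeatureMaps(NULL, NULL), class = "inputError")
  expect_error(fuseFeatureMaps(f, array(0, c(3, 2, 1, 1))),
               class = "shapeError")
  expect_error(fuseFeatureMaps(f, f, 0, 0), class = "degenerateWeightError")
})

test_that("fusion coefficients sum to one and fuse is linear", {
  set.seed(9)
  for (i in 1:25) {
    w <- rnorm(2)
    if (sum(abs(w)) < 1e-3) next
    f1 <- array(rnorm(18), c(3, 3, 2, 1))
    f2 <- array(rnorm(18), c(3, 3, 2, 1))
    y <- fuseFeatureMaps(f1, f2, w[1], w[2])
    a1 <- abs(w[1]) / sum(abs(w))
    expect_equal(y, a1 * f1 + (1 - a1) * f2, tolerance = 1e-12)
    # equal weights of any magnitude give the arithmetic mean
    c0 <- abs(rnorm(1)) + 0.1
    expect_equal(fuseFeatureMaps(f1, f2, c0, c0), (f1 + f2) / 2,
                 tolerance = 1e-12)
  }
})

test_that("resolution-normalization size arithmetic and identity", {
  x <- array(rnorm(40 * 40 * 2), c(40, 40, 2, 1))
  same <- resolutionNormalize(x, 1.0, 1.0, "to_base")
  expect_equal(dim(same$data), dim(x))
  expect_equal(same$data, x, tolerance = 1e-12) # s = 1 is the identity

  down <- resolutionNormalize(x, 0.8, 1.0, "to_base")
  expect_equal(down$size, c(32L, 32L)) # round(40 * 0.8)
  back <- resolutionNormalize(down$data, 0.8, 1.0, "to_native",
                              recordedSize = down$recordedSize)
  expect_equal(dim(back$data)[1:2], c(40L, 40L))

  expect_error(resolutionNormalize(x, -1, 1, "to_base"),
               class = "parameterError")
})

test_that("competitive dense block keeps spatial shape and flags NaN", {
  cfg <- tinyNetConfig()
  net <- buildFCNN(cfg, "coronal", seed = 2)
  x <- randStack(24, 24, 3, 2)
  lg <- forwardLogits(net, x, NULL, 1.0)
  expect_equal(dim(lg), c(24L, 24L, cfg$n_classes, 2L))
  expect_true(all(is.finite(lg)))
  xbad <- x; xbad[1] <- NaN
  expect_true(any(is.nan(forwardLogits(net, xbad, NULL, 1.0))))
})

test_that("maxout of identical maps is the map itself", {
  tp <- hyposeg:::.tapeNew()
  a <- hyposeg:::.tapeLeaf(tp, array(rnorm(16), c(2, 2, 2, 2)))
  y <- hyposeg:::.opMaxout(tp, a, a)
  expect_identical(y$value, a$value)
})

test_that("forward output is at native in-plane shape across resolutions", {
  net <- buildFCNN(tinyNetConfig(), "coronal", seed = 6)
  for (res in c(0.7, 0.8, 1.0, 1.1)) {
    for (hw in list(c(24L, 28L), c(33L, 24L))) {
      x <- array(rnorm(hw[1] * hw[2] * 3 * 1), c(hw, 3, 1))
      lg <- forwardLogits(net, x, x, res)
      expect_equal(dim(lg)[1:2], hw)
    }
  }
})

test_that("hetero-modal forward with absent T2 equals zeroed fusion weight", {
  net <- buildFCNN(tinyNetConfig(), "coronal", seed = 8)
  x1 <- randStack(seed = 21)
  x2 <- randStack(seed = 22)
  netZ <- net
  netZ@params$fuse.w2 <- 0
  expect_identical(forwardLogits(net, x1, NULL, 0.8),
                   forwardLogits(netZ, x1, x2, 0.8))
})

test_that("eval-mode forward is deterministic", {
  net <- buildFCNN(tinyNetConfig(), "axial", seed = 10)
  x <- randStack(seed = 30)
  expect_identical(forwardLogits(net, x, x, 0.9),
                   forwardLogits(net, x, x, 0.9))
})

test_that("parameter counting is exact on a closed-form case", {
  # one 3x3 conv 1->1 without bias is 9 parameters; verify through a
  # directly assembled parameter list
  net <- buildFCNN(tinyNetConfig(), "coronal", seed = 1)
  manual <- sum(vapply(net@params, length, 1L))
  expect_identical(countParameters(net), manual)
  expect_identical(length(array(0, c(3, 3, 1, 1))), 9L)

  # analytic count of one CDB chain: bn0 + 4x(conv+bias+bn) + 3 prelus
  cfg <- tinyNetConfig()
  cin <- cfg$stack_thickness; c <- cfg$outer_channels
  expected_t1 <- 2 * cin + (9 * cin * c + c + 2 * c) +
    3 * (c + 9 * c * c + c + 2 * c)
  got <- sum(vapply(grep("^t1\\.", names(net@params), value = TRUE),
                    function(nm) length(net@params[[nm]]), 1L))
  expect_identical(got, as.integer(expected_t1))
})

test_that("widened hetero-modal and narrow baseline parameter budgets", {
  hm <- buildFCNN(networkConfig(24, 80, 64), "coronal", seed = 1)
  bl <- buildFCNN(networkConfig(24, 64, 32, hetero_modal = FALSE),
                  "coronal", seed = 1)
  nHm <- countParameters(hm)
  nBl <- countParameters(bl)
  # regression values for this realization (millions)
  expect_equal(nHm / 1e6, 2.501, tolerance = 1e-3)
  expect_equal(nBl / 1e6, 1.4047, tolerance = 1e-3)
  # the hetero-modal net stays far below two dedicated models
  expect_lt(nHm, 2 * nBl)
})

test_that("checkpoints refuse plane and lookup-table mismatches", {
  dir <- withr::local_tempdir()
  lut <- toyLUT()
  net <- buildFCNN(tinyNetConfig(nClasses = nClassesFor(lut, "coronal")),
                   "coronal", lut, seed = 3)
  p <- file.path(dir, "ck.rds")
  saveCheckpoint(net, p)
  back <- loadCheckpoint(p, lut = lut, plane = "coronal")
  expect_identical(back@params, net@params)
  expect_error(loadCheckpoint(p, plane = "axial"), class = "checkpointError")
  expect_error(loadCheckpoint(p, lut = hypothalamusLUT()),
               class = "checkpointError")
})
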