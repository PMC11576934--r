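# independent brute-force oracles, written against the plain definitions
oracleDice <- function(m, p) {
  M <- which(m != 0); P <- which(p != 0)
  if (length(M) + length(P) == 0) return(1)
  2 * length(intersect(M, P)) / (length(M) + length(P))
}
oracleVS <- function(m, p) {
  M <- sum(m != 0); P <- sum(p != 0)
  if (M + P == 0) return(1)
  1 - abs(M - P) / (M + P)
}
# O(|M||P|) double loop over border voxels with quantile() percentiles
oracleHD95 <- function(m, p, vs) {
  bm <- hyposeg:::.borderVoxels(m); bp <- hyposeg:::.borderVoxels(p)
  am <- sweep(bm, 2, vs, "*"); ap <- sweep(bp, 2, vs, "*")
  dmin <- function(a, b) {
    out <- numeric(nrow(a))
    for (i in seq_len(nrow(a))) {
      best <- Inf
      for (j in seq_len(nrow(b)))
        best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
      out[i] <- best
    }
    out
  }
  max(quantile(dmin(am, ap), 0.95, type = 7),
      quantile(dmin(ap, am), 0.95, type = 7))
}

randMask <- function(d = c(9, 9, 9), n = 10) {
  m <- array(FALSE, d)
  m[sample(prod(d), n)] <- TRUE
  m
}

test_that("Dice and VS match their definitions on enumerated sets", {
  m <- array(FALSE, c(4, 4, 2)); p <- m
  m[1:4] <- TRUE            # |M| = 4
  p[2:7] <- TRUE            # |P| = 6, overlap 3
  expect_equal(diceCoefficient(m, p), 0.6)
  expect_equal(volumeSimilarity(m, p), 0.8)
  expect_equal(diceCoefficient(m, m), 1)
  expect_equal(volumeSimilarity(p, p), 1)
  # disjoint equal-sized masks: VS is maximal while Dice is zero
  q <- array(FALSE, c(4, 4, 2)); q[9:12] <- TRUE
  expect_equal(diceCoefficient(m, q), 0)
  expect_equal(volumeSimilarity(m, q), 1)
  # both empty is defined as perfect agreement
  e <- array(FALSE, c(4, 4, 2))
  expect_equal(diceCoefficient(e, e), 1)
  expect_equal(volumeSimilarity(e, e), 1)
  expect_error(diceCoefficient(m, array(FALSE, c(3, 3, 3))),
               class = "shapeError")
})

test_that("HD95 basics: identity, single voxels, voxel-size scaling", {
  m <- array(FALSE, c(8, 8, 8)); m[4, 4, 4] <- TRUE
  p <- array(FALSE, c(8, 8, 8)); p[4, 4, 7] <- TRUE
  expect_equal(hd95(m, m), 0)
  expect_equal(hd95(m, p, c(1, 1, 1)), 3)
  expect_equal(hd95(m, p, c(1, 1, 0.8)), 2.4) # anisotropy-aware
  expect_error(hd95(m, array(FALSE, c(8, 8, 8))),
               class = "undefinedMetricError")
})

test_that("metrics equal brute-force oracles on random small masks", {
  set.seed(31)
  worstGap <- 0
  for (i in 1:60) {
    m <- randMask(n = sample(5:15, 1))
    p <- randMask(n = sample(5:15, 1))
    vs3 <- sample(c(0.7, 0.8, 1.0), 3, replace = TRUE)
    expect_equal(diceCoefficient(m, p), oracleDice(m, p), tolerance = 1e-12)
    expect_equal(volumeSimilarity(m, p), oracleVS(m, p), tolerance = 1e-12)
    expect_lte(diceCoefficient(m, p), volumeSimilarity(m, p) + 1e-12)
    h <- hd95(m, p, vs3)
    expect_equal(h, oracleHD95(m, p, vs3), tolerance = 1e-9)
    # HD95 never exceeds the exact Hausdorff distance on the same sets
    bm <- sweep(hyposeg:::.borderVoxels(m), 2, vs3, "*")
    bp <- sweep(hyposeg:::.borderVoxels(p), 2, vs3, "*")
    d2 <- outer(rowSums(bm^2), rowSums(bp^2), "+") - 2 * bm %*% t(bp)
    hdFull <- sqrt(max(min(0, min(d2)) * 0,
                       max(apply(d2, 1, min), apply(d2, 2, min))))
    expect_lte(h, hdFull + 1e-9)
  }
})

test_that("Dice/VS ignore voxel size while HD95 scales linearly", {
  set.seed(32)
  m <- randMask(); p <- randMask()
  expect_identical(diceCoefficient(m, p), diceCoefficient(m, p))
  h1 <- hd95(m, p, c(1, 1, 1))
  h2 <- hd95(m, p, c(2, 2, 2))
  expect_equal(h2, 2 * h1, tolerance = 1e-9)
})

test_that("ICC(A,1) matches an aov-based computation and known cases", {
  x <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4) + 0.001)
  expect_gt(iccA1(x)$icc, 0.999)

  # independent mean squares through stats::aov on the long format
  aovICC <- function(m) {
    n <- nrow(m); k <- ncol(m)
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     meas = factor(rep(seq_len(k), each = n)))
    ms <- summary(aov(y ~ subj + meas, df))[[1]][["Mean Sq"]]
    (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k / n * (ms[2] - ms[3]))
  }
  expect_equal(iccA1(cbind(1:4, 2:5))$icc, aovICC(cbind(1:4, 2:5)),
               tolerance = 1e-9)
  set.seed(33)
  for (i in 1:50) {
    n <- sample(5:12, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k), n, k) + rnorm(n)
    expect_equal(iccA1(m)$icc, aovICC(m), tolerance = 1e-6)
  }
  # null case: no subject effect
  m0 <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(iccA1(m0)$icc), 0.2)
  ci <- iccA1(matrix(rnorm(40), 20, 2) + rnorm(20))$ci95
  expect_lt(ci[["lo"]], ci[["hi"]])
})

test_that("evaluatePair matches per-label oracles on a shifted copy", {
  ph <- generatePhantom(quickSpec(seed = 6, noiseSd = 0, bias = FALSE))
  ref <- conform(ph$labels)
  x <- volData(ref)
  shifted <- array(0L, dim(x))
  shifted[, , 2:dim(x)[3]] <- x[, , 1:(dim(x)[3] - 1)]
  pred <- new("BrainVolume", data = shifted, voxelSize = voxelSize(ref),
              affine = ref@affine, modality = "LABEL")
  rep <- evaluatePair(pred, ref, toyLUT())
  rows <- metricRows(rep)
  for (i in seq_len(nrow(rows))) {
    id <- rows$label_id[i]
    m <- x == id; p <- shifted == id
    if (!any(m) && !any(p)) {
      expect_false(rows$present[i])
      next
    }
    expect_equal(rows$dice[i], oracleDice(m, p), tolerance = 1e-12)
    expect_equal(rows$vs[i], oracleVS(m, p), tolerance = 1e-12)
  }
  perfect <- evaluatePair(ref, ref, toyLUT())
  pr <- metricRows(perfect)
  expect_true(all(pr$dice[pr$present] == 1))
  expect_true(all(pr$hd95_mm[pr$present] == 0))
  # absent-from-both labels are excluded from the aggregates
  expect_false(any(is.na(metricAggregates(perfect)$dice)))
})

test_that("paired Wilcoxon matches exact sign-flip enumeration", {
  set.seed(34)
  a <- round(rnorm(8), 2)
  b <- a + round(rnorm(8, 0.3), 2)
  d <- a - b
  # enumerate all 2^8 sign assignments of |d| ranks
  r <- rank(abs(d))
  Wobs <- sum(r[d > 0])
  Ws <- vapply(0:(2^8 - 1), function(mask) {
    s <- as.integer(intToBits(mask))[1:8]
    sum(r[s == 1])
  }, 0)
  pExact <- mean(abs(Ws - sum(r) / 2) >= abs(Wobs - sum(r) / 2))
  res <- pairedComparison(a, b, nTests = 1)
  expect_equal(res$p_raw, pExact, tolerance = 1e-12)
  expect_equal(res$p_bonferroni, res$p_raw)
  res3 <- pairedComparison(a, b, nTests = 5)
  expect_equal(res3$p_bonferroni, min(1, 5 * res$p_raw))
  deg <- pairedComparison(a, a)
  expect_true(deg$degenerate)
})
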