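#' Dice similarity coefficient
#'
#' `2|M:P| / (|M| + |P|)` between two binary masks of equal shape.
#' Both-empty pairs are defined as perfect agreement (1); an empty versus
#' non-empty pair scores 0.
#'
#' @param m,p logical/0-1 arrays of equal shape.
#' @return numeric in `[0, 1]`.
#' @export
diceCoefficient <- function(m, p) {
  .checkMaskPair(m, p)
  nm <- sum(m != 0); np <- sum(p != 0)
  if (nm + np == 0) return(1)
  2 * sum(m != 0 & p != 0) / (nm + np)
}

#' Volume similarity
#'
#' `1 - ||M| - |P|| / (|M| + |P|)`: agreement of mask sizes regardless of
#' localization, so it attains 1 even for disjoint equal-sized masks.
#' Always at least as large as the Dice coefficient.
#'
#' @inheritParams diceCoefficient
#' @return numeric in `[0, 1]`.
#' @export
volumeSimilarity <- function(m, p) {
  .checkMaskPair(m, p)
  nm <- sum(m != 0); np <- sum(p != 0)
  if (nm + np == 0) return(1)
  1 - abs(nm - np) / (nm + np)
}

.checkMaskPair <- function(m, p) {
  if (!identical(dim(m), dim(p)))
    .stopf("shapeError", "mask shapes differ")
}

# border voxels under 6-connectivity: mask voxels with at least one
# face-neighbour outside the mask (or on the array boundary)
.borderVoxels <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  interior <- array(TRUE, d)
  shift <- function(arr, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    out <- array(FALSE, d)
    if (by == 1) { src <- 1:(n - 1); dst <- 2:n }
    else { src <- 2:n; dst <- 1:(n - 1) }
    ref <- list(1:d[1], 1:d[2], 1:d[3])
    refS <- ref; refS[[ax]] <- src
    refD <- ref; refD[[ax]] <- dst
    out[refD[[1]], refD[[2]], refD[[3]]] <-
      arr[refS[[1]], refS[[2]], refS[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(1, -1))
    interior <- interior & shift(m, ax, by)
  which(m & !interior, arr.ind = TRUE)
}

# 95th percentile (linear interpolation between order statistics) of
# directed nearest-neighbour distances from points a to points b (mm)
.directed95 <- function(a, b, chunk = 512L) {
  mins <- numeric(nrow(a))
  for (start in seq(1L, nrow(a), by = chunk)) {
    sel <- seq(start, min(start + chunk - 1L, nrow(a)))
    d2 <- outer(rowSums(a[sel, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[sel, , drop = FALSE] %*% t(b)
    d2[d2 < 1e-9] <- 0 # cancellation noise: coincident points are distance 0
    mins[sel] <- sqrt(apply(d2, 1, min))
  }
  s <- sort(mins)
  n <- length(s)
  h <- (n - 1) * 0.95
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Symmetric HD95 over the border voxels (6-connectivity) of each mask:
#' `max(d95(M,P), d95(P,M))` where `d95` is the 95th percentile (linear
#' interpolation between order statistics) of minimum Euclidean distances
#' in mm, anisotropy-aware through the voxel size. Zero for identical
#' masks; undefined (error) if either mask is empty.
#'
#' @inheritParams diceCoefficient
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @return non-negative distance in mm.
#' @export
hd95 <- function(m, p, voxelSize = c(1, 1, 1)) {
  .checkMaskPair(m, p)
  if (sum(m != 0) == 0 || sum(p != 0) == 0)
    .stopf("undefinedMetricError", "HD95 is undefined for an empty mask")
  bm <- sweep(.borderVoxels(m), 2, voxelSize, "*")
  bp <- sweep(.borderVoxels(p), 2, voxelSize, "*")
  max(.directed95(bm, bp), .directed95(bp, bm))
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way, absolute-agreement, single-measure intraclass correlation
#' (McGraw and Wong), `(MS_R - MS_E) / (MS_R + (k-1) MS_E + k/n (MS_C -
#' MS_E))`, computed from the two-way ANOVA decomposition of an n-subject
#' by k-measurement table, with the standard F-based 95% confidence
#' interval.
#'
#' @param x numeric matrix, n subjects (rows) x k repeated measurements
#'   (columns), no missing cells.
#' @param conf confidence level.
#' @return list with `icc`, `ci95 = c(lo, hi)` and the mean squares.
#' @export
iccA1 <- function(x, conf = 0.95) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L || anyNA(x))
    .stopf("inputError", "need a complete n>=2 by k>=2 table")
  mu <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  SSR <- k * sum((rowm - mu)^2)
  SSC <- n * sum((colm - mu)^2)
  SST <- sum((x - mu)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (abs(denom) < 1e-300)
    .stopf("undefinedMetricError", "zero total variance")
  icc <- (MSR - MSE) / denom

  # F-based interval (McGraw & Wong A,1)
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  Fstar <- (a * MSC + b * MSE)
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = .clamp(icc, -1, 1), ci95 = c(lo = lo, hi = hi),
       MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Per-structure metric report between two label volumes
#'
#' Computes Dice, volume similarity and HD95 per label, plus unweighted
#' region-group and global means over structures present in at least one
#' map; labels absent from both maps are flagged not-applicable and
#' excluded from the aggregates. HD95 is reported NA when either side of
#' a present structure is empty.
#'
#' @param pred,ref `LABEL` [BrainVolume-class] objects on the same grid.
#' @param lut a [LabelLookup-class].
#' @return a [MetricsReport-class].
#' @export
evaluatePair <- function(pred, ref, lut) {
  if (!identical(dim(volData(pred)), dim(volData(ref))))
    .stopf("shapeError", "label volumes differ in shape")
  tb <- lutTable(lut)
  known <- c(0L, tb$id)
  lp <- volData(pred); lr <- volData(ref)
  if (!all(unique(as.integer(lp)) %in% known) ||
      !all(unique(as.integer(lr)) %in% known))
    .stopf("labelError", "label outside the lookup table")
  vs3 <- voxelSize(ref)
  rows <- do.call(rbind, lapply(seq_len(nrow(tb)), function(i) {
    id <- tb$id[i]
    m <- lr == id; p <- lp == id
    present <- any(m) || any(p)
    if (!present)
      return(data.frame(label_id = id, name = tb$name[i],
                        region = tb$region[i], dice = NA_real_,
                        vs = NA_real_, hd95_mm = NA_real_, present = FALSE))
    h <- if (any(m) && any(p)) hd95(m, p, vs3) else NA_real_
    data.frame(label_id = id, name = tb$name[i], region = tb$region[i],
               dice = diceCoefficient(m, p), vs = volumeSimilarity(m, p),
               hd95_mm = h, present = TRUE)
  }))
  pres <- rows[rows$present, , drop = FALSE]
  aggRegion <- do.call(rbind, lapply(unique(pres$region), function(rg) {
    sub <- pres[pres$region == rg, , drop = FALSE]
    data.frame(level = rg, dice = mean(sub$dice), vs = mean(sub$vs),
               hd95_mm = mean(sub$hd95_mm, na.rm = TRUE))
  }))
  agg <- rbind(aggRegion,
               data.frame(level = "global", dice = mean(pres$dice),
                          vs = mean(pres$vs),
                          hd95_mm = mean(pres$hd95_mm, na.rm = TRUE)))
  new("MetricsReport", rows = rows, aggregates = agg)
}

#' Paired two-sided Wilcoxon signed-rank comparison with Bonferroni
#' correction
#'
#' @param scoresA,scoresB paired score vectors (length >= 5).
#' @param nTests number of tests in the family for the Bonferroni factor.
#' @return list with `p_raw`, `p_bonferroni`, `statistic`, `degenerate`.
#' @export
pairedComparison <- function(scoresA, scoresB, nTests = 1L) {
  if (length(scoresA) != length(scoresB) || length(scoresA) < 5L)
    .stopf("inputError", "need paired vectors of equal length >= 5")
  if (nTests < 1L) .stopf("inputError", "nTests must be >= 1")
  d <- scoresA - scoresB
  if (all(d == 0))
    return(list(p_raw = NA_real_, p_bonferroni = NA_real_,
                statistic = NA_real_, degenerate = TRUE))
  wt <- suppressWarnings(wilcox.test(scoresA, scoresB, paired = TRUE,
                                     alternative = "two.sided"))
  list(p_raw = wt$p.value, p_bonferroni = min(1, nTests * wt$p.value),
       statistic = unname(wt$statistic), degenerate = FALSE)
}

#' Write a metrics report to CSV / JSON
#'
#' @param report a [MetricsReport-class].
#' @param csvPath,jsonPath output paths (either may be `NULL`).
#' @export
writeMetricsReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    write.csv(metricRows(report), csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(rows = metricRows(report),
                              aggregates = metricAggregates(report)),
                         jsonPath, dataframe = "rows", digits = NA,
                         na = "null")
  invisible(report)
}
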