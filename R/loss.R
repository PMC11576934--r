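#' Median-frequency class weights
#'
#' `w_c = median(f) / f_c` with `f_c` the relative voxel frequency of
#' class `c` among classes that occur; classes with zero count get weight
#' 0. Balances the cross-entropy term against strong class imbalance
#' (background dominates small sub-structures by orders of magnitude).
#'
#' @param labelHistogram named numeric vector of voxel counts per class.
#' @return named numeric weights.
#' @export
medianFrequencyWeights <- function(labelHistogram) {
  if (length(labelHistogram) == 0L)
    .stopf("inputError", "empty label histogram")
  cnt <- as.numeric(labelHistogram)
  if (all(cnt == 0)) .stopf("inputError", "all counts are zero")
  pos <- cnt > 0
  f <- cnt[pos] / sum(cnt)
  w <- rep(0, length(cnt))
  w[pos] <- median(f) / f
  names(w) <- names(labelHistogram)
  w
}

# softmax over the class axis of (H,W,C,N), computed pixel-wise
.softmax4 <- function(logits) {
  d <- dim(logits)
  npix <- d[1] * d[2] * d[4]
  lm <- matrix(aperm(logits, c(1, 2, 4, 3)), npix, d[3])
  lm <- lm - apply(lm, 1, max)
  pm <- exp(lm)
  pm <- pm / rowSums(pm)
  aperm(array(pm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

#' Combined weighted cross-entropy and soft-Dice loss
#'
#' Unweighted sum of a median-frequency-weighted cross-entropy (mean over
#' pixels) and a soft-Dice loss `1 - mean_c 2*sum(p*g) / (sum(p) + sum(g)
#' + eps)` over foreground classes present in the target. Returns the loss
#' and its gradient with respect to the logits, which seeds the network
#' backward pass.
#'
#' @param logits (H,W,C,N) array.
#' @param target (H,W,N) integer array of 1-based class indices (1 =
#'   background).
#' @param classWeights numeric(C) cross-entropy class weights.
#' @param eps Dice smoothing constant.
#' @return list(loss, grad, ce, dice).
#' @export
combinedLoss <- function(logits, target, classWeights, eps = 1e-6) {
  d <- dim(logits)
  C <- d[3]
  tv <- as.integer(target)
  if (any(tv < 1L) || any(tv > C))
    .stopf("labelError", "target class index outside [1, n_classes]")
  npix <- d[1] * d[2] * d[4]

  # softmax, stably, as (pixel x class) matrix
  lm <- matrix(aperm(logits, c(1, 2, 4, 3)), npix, C)
  lm <- lm - apply(lm, 1, max)
  pm <- exp(lm)
  pm <- pm / rowSums(pm)

  onehotIdx <- cbind(seq_len(npix), tv)
  wpix <- classWeights[tv]
  wsum <- sum(wpix)
  if (wsum <= 0) .stopf("inputError", "all class weights are zero on target")
  py <- pmax(pm[onehotIdx], 1e-12)
  ce <- sum(wpix * -log(py)) / wsum # weighted mean over pixels

  gm <- matrix(0, npix, C)
  gm[onehotIdx] <- 1

  # classes present in the target, background included: the background
  # Dice term is what penalizes foreground false positives
  fg <- which(colSums(gm) > 0)
  diceGrad <- matrix(0, npix, C)
  diceVals <- numeric(0)
  if (length(fg) > 0) {
    for (c in fg) {
      P <- sum(pm[, c]); G <- sum(gm[, c]); A <- sum(pm[, c] * gm[, c])
      B <- P + G + eps
      diceVals <- c(diceVals, 2 * A / B)
      diceGrad[, c] <- -(2 * (gm[, c] * B - A) / B^2) / length(fg)
    }
  }
  diceLoss <- if (length(fg) > 0) 1 - mean(diceVals) else 0

  # d(loss)/d(logits): CE part + Dice part chained through softmax
  dce <- (pm - gm) * (wpix / wsum)
  dot <- rowSums(diceGrad * pm)
  ddice <- pm * (diceGrad - dot)
  gmat <- dce + ddice
  grad <- aperm(array(gmat, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(loss = ce + diceLoss, grad = grad, ce = ce, dice = diceLoss)
}
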