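# Differentiable layers recorded on the autodiff tape. Feature maps are
# (H, W, C, N) column-major arrays. Channel-wise broadcasts exploit the
# layout: rep(v, each = H*W) recycles across samples.

.opConv2d <- function(tape, x, w, b) {
  y <- .conv2d_fw(x$value, w$value, b$value)
  .tapeNode(tape, y, list(x, w, b), bwd = local({
    xv <- x$value; wv <- w$value
    function(g) {
      r <- .conv2d_bw(xv, wv, g)
      list(r$gx, r$gw, r$gb)
    }
  }))
}

.opPrelu <- function(tape, x, a) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  neg <- x$value < 0
  fac <- 1 + neg * rep(a$value - 1, each = hw) # slope below 0, 1 above
  y <- x$value * fac
  .tapeNode(tape, y, list(x, a), bwd = local({
    xv <- x$value; C <- d[3]; N <- d[4]
    function(g) {
      gx <- g * fac
      ga <- rowSums(matrix(colSums(matrix(g * xv * neg, hw, C * N)), C, N))
      list(gx, ga)
    }
  }))
}

# Batch normalization. In training mode uses batch moments (biased
# variance) and updates running stats in `state`; in eval mode uses the
# stored running moments, keeping inference deterministic.
.opBatchNorm <- function(tape, x, gamma, beta, state, name, training,
                         eps = 1e-5, momentum = 0.1) {
  d <- dim(x$value)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- hw * N
  chSum <- function(v) rowSums(matrix(colSums(matrix(v, hw, C * N)), C, N))
  if (training) {
    mu <- chSum(x$value) / m
    va <- chSum(x$value^2) / m - mu^2
    va <- pmax(va, 0)
    st <- state$stats[[name]]
    unb <- if (m > 1) m / (m - 1) else 1
    state$stats[[name]] <- list(
      mean = (1 - momentum) * st$mean + momentum * mu,
      var = (1 - momentum) * st$var + momentum * va * unb)
  } else {
    st <- state$stats[[name]]
    mu <- st$mean; va <- st$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (x$value - rep(mu, each = hw)) * rep(invstd, each = hw)
  y <- xhat * rep(gamma$value, each = hw) + rep(beta$value, each = hw)
  .tapeNode(tape, y, list(x, gamma, beta), bwd = function(g) {
    dgamma <- chSum(g * xhat)
    dbeta <- chSum(g)
    dxhat <- g * rep(gamma$value, each = hw)
    if (training) {
      s1 <- chSum(dxhat)
      s2 <- chSum(dxhat * xhat)
      gx <- (dxhat - rep(s1 / m, each = hw) -
               xhat * rep(s2 / m, each = hw)) * rep(invstd, each = hw)
    } else {
      gx <- dxhat * rep(invstd, each = hw)
    }
    list(gx, dgamma, dbeta)
  })
}

# competitive (elementwise-maximum) merge; ties route to the first input
.opMaxout <- function(tape, a, b) {
  take_a <- a$value >= b$value
  y <- a$value * take_a + b$value * !take_a
  .tapeNode(tape, y, list(a, b),
            bwd = function(g) list(g * take_a, g * !take_a))
}

.opMaxPool <- function(tape, x) {
  r <- .maxpool_fw(x$value)
  d <- dim(x$value)
  nd <- .tapeNode(tape, r$y, list(x), bwd = function(g)
    list(.maxpool_scatter(g, r$idx, d[1], d[2])))
  list(node = nd, idx = r$idx, inSize = d[1:2])
}

# index unpooling onto the encoder's argmax positions
.opUnpool <- function(tape, x, idx, outSize) {
  d <- dim(x$value)
  y <- .maxpool_scatter(x$value, idx, outSize[1], outSize[2])
  .tapeNode(tape, y, list(x), bwd = function(g)
    list(.maxpool_gather(g, idx, d[1], d[2])))
}

# bilinear spatial resize to an explicit target size (separable 1D maps)
.opResize <- function(tape, x, outSize) {
  d <- dim(x$value)
  if (all(d[1:2] == outSize)) return(x)
  Ah <- .interpMatrix(d[1], outSize[1])
  Aw <- .interpMatrix(d[2], outSize[2])
  y <- .applyAlongAxis(.applyAlongAxis(x$value, Ah, 1), Aw, 2)
  .tapeNode(tape, y, list(x), bwd = function(g)
    list(.applyAlongAxis(.applyAlongAxis(g, t(Ah), 1), t(Aw), 2)))
}

.opConcatChannels <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  .tapeNode(tape, y, list(a, b), bwd = function(g)
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE]))
}

# Normalized fusion of modality branches: a_m = |w_m| / (|w_t1| + |w_t2|).
# With one branch absent its weight is forced to zero and the output is
# the other branch bit-for-bit (the coefficient is exactly 1).
.opFuse <- function(tape, f1, f2, w1, w2) {
  if (is.null(f1) && is.null(f2))
    .stopf("inputError", "fusion needs at least one modality")
  if (is.null(f2)) {
    return(.tapeNode(tape, f1$value, list(f1), bwd = function(g) list(g)))
  }
  if (is.null(f1)) {
    return(.tapeNode(tape, f2$value, list(f2), bwd = function(g) list(g)))
  }
  if (!identical(dim(f1$value), dim(f2$value)))
    .stopf("shapeError", "fusion inputs differ in shape")
  s <- abs(w1$value) + abs(w2$value)
  if (s == 0)
    .stopf("degenerateWeightError",
           "both fusion weights are zero with both modalities present")
  a1 <- abs(w1$value) / s
  a2 <- abs(w2$value) / s
  y <- a1 * f1$value + a2 * f2$value
  .tapeNode(tape, y, list(f1, f2, w1, w2), bwd = function(g) {
    diffSum <- sum(g * f1$value) - sum(g * f2$value)
    gw1 <- sign(w1$value) * abs(w2$value) / s^2 * diffSum
    gw2 <- -sign(w2$value) * abs(w1$value) / s^2 * diffSum
    list(a1 * g, a2 * g, gw1, gw2)
  })
}

#' Fuse modality feature maps with normalized learnable weights
#'
#' The fusion module output is `a1 * F_T1 + a2 * F_T2` with
#' `a_m = |w_m| / (|w_t1| + |w_t2|)`, so the coefficients always sum to 1.
#' An absent modality forces its weight to zero, making the output
#' identical to the present branch to machine precision.
#'
#' @param fT1,fT2 (H,W,C,N) arrays or `NULL` for an absent modality.
#' @param wT1,wT2 scalar fusion weights (initialized at 0.5 in a fresh
#'   network).
#' @return fused array.
#' @export
fuseFeatureMaps <- function(fT1, fT2, wT1 = 0.5, wT2 = 0.5) {
  tp <- .tapeNew()
  f1 <- if (is.null(fT1)) NULL else .tapeLeaf(tp, fT1)
  f2 <- if (is.null(fT2)) NULL else .tapeLeaf(tp, fT2)
  if (is.null(fT1)) wT1 <- 0
  if (is.null(fT2)) wT2 <- 0
  .opFuse(tp, f1, f2, .tapeLeaf(tp, wT1), .tapeLeaf(tp, wT2))$value
}

#' Resolution-normalization size arithmetic and feature-map resize
#'
#' Maps a feature map between its native in-plane resolution and the
#' network base resolution by bilinear interpolation. For `to_base` the
#' scale is `s = (native/base) * jitter` and the output size is
#' `round(size * s)` (at least 1); the pre-normalization size is recorded
#' so that `to_native` restores exactly the recorded grid, making the
#' round-trip the identity for any input size.
#'
#' @param x (H,W,C,N) array.
#' @param nativeRes,baseRes positive mm.
#' @param direction `"to_base"` or `"to_native"`.
#' @param jitter positive scale-augmentation factor (1 = none).
#' @param recordedSize for `to_native`: the (H,W) recorded by the matching
#'   `to_base` call.
#' @return list with `data` and `size` (and `recordedSize` on `to_base`).
#' @export
resolutionNormalize <- function(x, nativeRes, baseRes,
                                direction = c("to_base", "to_native"),
                                jitter = 1, recordedSize = NULL) {
  direction <- match.arg(direction)
  if (nativeRes <= 0 || baseRes <= 0 || jitter <= 0)
    .stopf("parameterError", "resolutions and jitter must be positive")
  d <- dim(x)
  if (direction == "to_base") {
    out <- .rnOutSize(d[1:2], nativeRes, baseRes, jitter)
    rec <- d[1:2]
  } else {
    out <- if (!is.null(recordedSize)) recordedSize
           else .rnOutSize(d[1:2], baseRes, nativeRes, 1 / jitter)
    rec <- NULL
  }
  tp <- .tapeNew()
  y <- .opResize(tp, .tapeLeaf(tp, x), out)$value
  list(data = y, size = out, recordedSize = rec)
}

.rnOutSize <- function(size, fromRes, toRes, jitter = 1) {
  s <- (fromRes / toRes) * jitter
  if (s <= 0) .stopf("parameterError", "non-positive scale factor")
  pmax(1L, as.integer(round(size * s)))
}
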