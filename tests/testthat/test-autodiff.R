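# Every layer's analytic gradient is compared against central finite
# differences through a scalar readout sum(g * y).

numGrad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

checkOp <- function(build, inputs, tol = 1e-6) {
  # build(tape, leaves...) -> output node
  tp <- hyposeg:::.tapeNew()
  leaves <- lapply(inputs, function(x) hyposeg:::.tapeLeaf(tp, x))
  out <- do.call(build, c(list(tp), leaves))
  set.seed(99)
  g <- array(rnorm(length(out$value)), dim(out$value) %||% length(out$value))
  hyposeg:::.tapeBackward(tp, out, g)
  for (k in seq_along(inputs)) {
    f <- function(x) {
      tp2 <- hyposeg:::.tapeNew()
      l2 <- lapply(seq_along(inputs), function(j)
        hyposeg:::.tapeLeaf(tp2, if (j == k) x else inputs[[j]]))
      sum(g * do.call(build, c(list(tp2), l2))$value)
    }
    num <- numGrad(f, inputs[[k]])
    an <- leaves[[k]]$grad
    if (is.null(an)) an <- inputs[[k]] * 0
    expect_equal(as.vector(an), as.vector(num), tolerance = tol,
                 label = sprintf("analytic grad of input %d", k))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("conv2d forward matches direct summation and gradients check out", {
  set.seed(11)
  x <- array(rnorm(5 * 4 * 2 * 1), c(5, 4, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  y <- hyposeg:::.conv2d_fw(x, w, b)
  # direct same-padding convolution at two positions
  direct <- function(h, wd, o) {
    acc <- b[o]
    for (ki in 1:3) for (kj in 1:3) for (c in 1:2) {
      sh <- h + ki - 2; sw <- wd + kj - 2
      if (sh >= 1 && sh <= 5 && sw >= 1 && sw <= 4)
        acc <- acc + x[sh, sw, c, 1] * w[ki, kj, c, o]
    }
    acc
  }
  expect_equal(y[2, 3, 1, 1], direct(2, 3, 1), tolerance = 1e-12)
  expect_equal(y[1, 1, 2, 1], direct(1, 1, 2), tolerance = 1e-12)
  expect_equal(y[5, 4, 3, 1], direct(5, 4, 3), tolerance = 1e-12)

  checkOp(function(tp, xn, wn, bn) hyposeg:::.opConv2d(tp, xn, wn, bn),
          list(x, w, b))
})

test_that("prelu, maxout, resize, concat and unpool gradients check out", {
  set.seed(12)
  x <- array(rnorm(24), c(3, 4, 2, 1))
  a <- c(0.3, -0.2)
  checkOp(function(tp, xn, an) hyposeg:::.opPrelu(tp, xn, an), list(x, a))

  y2 <- array(rnorm(24), c(3, 4, 2, 1))
  checkOp(function(tp, an, bn) hyposeg:::.opMaxout(tp, an, bn), list(x, y2))

  checkOp(function(tp, xn) hyposeg:::.opResize(tp, xn, c(5L, 3L)), list(x))
  checkOp(function(tp, xn) hyposeg:::.opResize(tp, xn, c(2L, 6L)), list(x))

  checkOp(function(tp, an, bn) hyposeg:::.opConcatChannels(tp, an, bn),
          list(x, array(rnorm(12), c(3, 4, 1, 1))))

  x4 <- array(rnorm(4 * 6 * 2), c(4, 6, 2, 1))
  pool <- hyposeg:::.maxpool_fw(x4)
  checkOp(function(tp, xn) hyposeg:::.opUnpool(tp, xn, pool$idx, c(4L, 6L)),
          list(pool$y))
})

test_that("maxpool selects window maxima and routes gradients there", {
  x <- array(0, c(4, 4, 1, 1))
  x[1:4, 1:4, 1, 1] <- matrix(1:16, 4, 4)
  r <- hyposeg:::.maxpool_fw(x)
  expect_equal(as.vector(r$y), c(6, 8, 14, 16)) # column-major 2x2 maxima
  checkOp(function(tp, xn) hyposeg:::.opMaxPool(tp, xn)$node,
          list(array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))))
})

test_that("batch-norm train and eval gradients check out", {
  set.seed(13)
  x <- array(rnorm(36), c(3, 3, 2, 2))
  gamma <- c(1.2, 0.7); beta <- c(0.1, -0.4)
  for (training in c(TRUE, FALSE)) {
    st0 <- list(stats = list(bn = list(mean = c(0.2, -0.1), var = c(1.3, 0.8))))
    checkOp(function(tp, xn, gn, bn) {
      state <- as.environment(list(stats = st0$stats))
      hyposeg:::.opBatchNorm(tp, xn, gn, bn, state, "bn", training)
    }, list(x, gamma, beta), tol = 1e-5)
  }
})

test_that("fusion gradients including the global weights check out", {
  set.seed(14)
  f1 <- array(rnorm(24), c(3, 4, 2, 1))
  f2 <- array(rnorm(24), c(3, 4, 2, 1))
  for (w in list(c(0.5, 0.5), c(0.3, 0.1), c(-0.4, 0.2)))
    checkOp(function(tp, a, b, w1, w2) hyposeg:::.opFuse(tp, a, b, w1, w2),
            list(f1, f2, w[1], w[2]))
})

test_that("combined loss gradient matches finite differences", {
  set.seed(15)
  d <- c(5, 4, 3, 2)
  logits <- array(rnorm(prod(d)), d)
  target <- array(sample(1:3, 5 * 4 * 2, TRUE), c(5, 4, 2))
  cw <- c(0.2, 1, 3)
  r <- combinedLoss(logits, target, cw)
  num <- numGrad(function(l) combinedLoss(l, target, cw)$loss, logits)
  expect_equal(as.vector(r$grad), as.vector(num), tolerance = 1e-5)
})

test_that("whole-network gradients agree with finite differences", {
  set.seed(16)
  cfg <- tinyNetConfig()
  net <- buildFCNN(cfg, "coronal", seed = 5)
  x1 <- randStack(seed = 41)
  x2 <- randStack(seed = 42)
  target <- array(sample(1:4, 24 * 24 * 2, TRUE), c(24, 24, 2))
  cw <- rep(1, 4)
  fw <- hyposeg:::.forwardFCNN(net, x1, x2, 0.8, training = TRUE,
                               jitter = 1.07)
  ls <- combinedLoss(fw$logits$value, target, cw)
  hyposeg:::.tapeBackward(fw$tape, fw$logits, ls$grad)
  lossAt <- function(params) {
    f <- hyposeg:::.forwardFCNN(hyposeg:::netWith(net, params), x1, x2, 0.8,
                                training = TRUE, jitter = 1.07)
    combinedLoss(f$logits$value, target, cw)$loss
  }
  eps <- 1e-6
  nms <- c("t1.conv1.w", "t2.conv4.b", "enc2.bn0.gamma", "enc4.conv2.w",
           "bott.conv3.w", "dec3.act2.a", "dec1.conv1.w", "cls.w", "cls.b")
  set.seed(17)
  for (nm in nms) {
    i <- sample(length(net@params[[nm]]), 1)
    p1 <- net@params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- net@params; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
    an <- fw$leaves[[nm]]$grad[i]
    expect_equal(an, num, tolerance = 1e-3, label = nm)
  }
})
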