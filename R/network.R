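#' Network configuration
#'
#' Channel widths follow the widened hetero-modal layout: `inner_channels`
#' inside the base-resolution competitive dense blocks (CDBs) and
#' `outer_channels` in the first and last blocks, which operate at the
#' native image resolution on either side of the network-integrated
#' resolution-normalization.
#'
#' @param n_classes number of output classes of the 1x1 classifier.
#' @param inner_channels channels of the base-resolution CDBs (default 80).
#' @param outer_channels channels of the native-resolution CDBs (default
#'   64).
#' @param stack_thickness odd multi-slice input thickness (default 7).
#' @param base_resolution internal base resolution in mm (default 1.0).
#' @param n_scales number of scale transitions (default 5: one
#'   resolution-normalization plus four 2x2 poolings).
#' @param convs_per_block PReLU-Conv-BN layers per CDB (default 4).
#' @param kernel 2D convolution kernel size (default 3x3).
#' @param hetero_modal build modality-specific T1/T2 input blocks plus the
#'   fusion module (`TRUE`) or a single-modality input block (`FALSE`).
#' @return validated config list.
#' @export
networkConfig <- function(n_classes, inner_channels = 80L,
                          outer_channels = 64L, stack_thickness = 7L,
                          base_resolution = 1.0, n_scales = 5L,
                          convs_per_block = 4L, kernel = c(3L, 3L),
                          hetero_modal = TRUE) {
  if (inner_channels < outer_channels || outer_channels < 1L)
    .stopf("configError", "need inner_channels >= outer_channels >= 1")
  if (base_resolution <= 0) .stopf("configError", "base_resolution must be > 0")
  if (!.isOdd(stack_thickness))
    .stopf("configError", "stack_thickness must be odd")
  if (n_classes < 2L) .stopf("configError", "need at least two classes")
  list(n_classes = as.integer(n_classes),
       inner_channels = as.integer(inner_channels),
       outer_channels = as.integer(outer_channels),
       stack_thickness = as.integer(stack_thickness),
       base_resolution = base_resolution, n_scales = as.integer(n_scales),
       convs_per_block = as.integer(convs_per_block),
       kernel = as.integer(kernel), hetero_modal = isTRUE(hetero_modal))
}

#' Number of classes for a plane under a lookup table
#'
#' Axial and coronal networks see every label; the sagittal network sees
#' the laterally merged table. One extra class covers the background.
#'
#' @param lut a [LabelLookup-class].
#' @param plane slicing plane.
#' @param background include a background class (default TRUE).
#' @return integer class count.
#' @export
nClassesFor <- function(lut, plane, background = TRUE) {
  n <- if (plane == "sagittal") nrow(lutTable(mergeLateralLabels(lut)$merged))
       else nrow(lutTable(lut))
  as.integer(n + background)
}

# ---- parameter initialization -------------------------------------------

.cdbInit <- function(params, stats, prefix, cin, cout, cfg, inputVariant) {
  kh <- cfg$kernel[1]; kw <- cfg$kernel[2]
  he <- function(ci) array(rnorm(kh * kw * ci * cout, 0,
                                 sqrt(2 / (kh * kw * ci))),
                           c(kh, kw, ci, cout))
  if (inputVariant) {
    params[[paste0(prefix, ".bn0.gamma")]] <- rep(1, cin)
    params[[paste0(prefix, ".bn0.beta")]] <- rep(0, cin)
    stats[[paste0(prefix, ".bn0")]] <- list(mean = rep(0, cin), var = rep(1, cin))
  } else {
    params[[paste0(prefix, ".act1.a")]] <- rep(0.25, cin)
  }
  ci <- cin
  for (l in seq_len(cfg$convs_per_block)) {
    if (l > 1L) params[[paste0(prefix, ".act", l, ".a")]] <- rep(0.25, cout)
    params[[paste0(prefix, ".conv", l, ".w")]] <- he(ci)
    params[[paste0(prefix, ".conv", l, ".b")]] <- rep(0, cout)
    params[[paste0(prefix, ".bn", l, ".gamma")]] <- rep(1, cout)
    params[[paste0(prefix, ".bn", l, ".beta")]] <- rep(0, cout)
    stats[[paste0(prefix, ".bn", l)]] <- list(mean = rep(0, cout),
                                              var = rep(1, cout))
    ci <- cout
  }
  list(params = params, stats = stats)
}

.blockPlan <- function(cfg) {
  ic <- cfg$inner_channels; oc <- cfg$outer_channels
  th <- cfg$stack_thickness
  plan <- list()
  if (cfg$hetero_modal) {
    plan$t1 <- list(cin = th, cout = oc, variant = TRUE)
    plan$t2 <- list(cin = th, cout = oc, variant = TRUE)
  } else {
    plan$inp <- list(cin = th, cout = oc, variant = TRUE)
  }
  plan$enc2 <- list(cin = oc, cout = ic, variant = TRUE)
  for (b in c("enc3", "enc4", "enc5", "bott", "dec5", "dec4", "dec3", "dec2"))
    plan[[b]] <- list(cin = ic, cout = ic, variant = FALSE)
  plan$dec1 <- list(cin = ic + oc, cout = oc, variant = FALSE)
  plan
}

#' Build a hetero-modal resolution-independent F-CNN
#'
#' U-Net layout with five competitive dense blocks per arm separated by a
#' bottleneck CDB. The first scale transition is the resolution-
#' normalization from native to base resolution, the remaining transitions
#' are 2x2 max-pooling with index-preserving unpooling in the decoder.
#' Base-resolution skip connections compete by elementwise maximum; the
#' native-level skip (whose widths differ) is fused by channel
#' concatenation into the last decoder block. A 1x1 convolution maps to
#' class logits; softmax is applied at inference.
#'
#' @param cfg a [networkConfig()].
#' @param plane slicing plane this network serves.
#' @param lut [LabelLookup-class] used for the checkpoint fingerprint (the
#'   sagittal network is expected to be built with the merged table).
#' @param seed RNG seed for weight initialization.
#' @return an [HMVINN-class].
#' @export
buildFCNN <- function(cfg, plane = "coronal", lut = NULL, seed = 42L) {
  .checkPlane(plane)
  params <- list()
  stats <- list()
  .withSeed(.deriveSeed(seed, paste0("init.", plane)), {
    for (nm in names(.blockPlan(cfg))) {
      b <- .blockPlan(cfg)[[nm]]
      r <- .cdbInit(params, stats, nm, b$cin, b$cout, cfg, b$variant)
      params <- r$params; stats <- r$stats
    }
    if (cfg$hetero_modal) {
      params[["fuse.w1"]] <- 0.5
      params[["fuse.w2"]] <- 0.5
    }
    oc <- cfg$outer_channels
    params[["cls.w"]] <- array(rnorm(oc * cfg$n_classes, 0, sqrt(2 / oc)),
                               c(1, 1, oc, cfg$n_classes))
    params[["cls.b"]] <- rep(0, cfg$n_classes)
  })
  new("HMVINN", cfg = cfg, params = params, bnStats = stats, plane = plane,
      lutHash = if (is.null(lut)) "unbound" else .lutFingerprint(lut),
      epochsTrained = 0L)
}

#' @rdname countParameters
#' @export
setMethod("countParameters", "HMVINN", function(object)
  sum(vapply(object@params, length, 1L)))

# ---- forward pass --------------------------------------------------------

.cdbForward <- function(tape, x, prefix, lv, state, cfg, inputVariant,
                        training) {
  P <- function(nm) lv[[paste0(prefix, ".", nm)]]
  m <- NULL
  h <- x
  for (l in seq_len(cfg$convs_per_block)) {
    a <- if (l == 1L) {
      if (inputVariant)
        .opBatchNorm(tape, h, P("bn0.gamma"), P("bn0.beta"), state,
                     paste0(prefix, ".bn0"), training)
      else .opPrelu(tape, h, P("act1.a"))
    } else .opPrelu(tape, m, P(paste0("act", l, ".a")))
    cv <- .opConv2d(tape, a, P(paste0("conv", l, ".w")),
                    P(paste0("conv", l, ".b")))
    bn <- .opBatchNorm(tape, cv, P(paste0("bn", l, ".gamma")),
                       P(paste0("bn", l, ".beta")), state,
                       paste0(prefix, ".bn", l), training)
    # competitive merge of intermediate outputs; the last layer's output
    # leaves the block unmerged
    m <- if (l == 1L || l == cfg$convs_per_block) bn
         else .opMaxout(tape, m, bn)
  }
  m
}

# Full forward pass. xT1 / xT2 are (H, W, S, N) arrays (multi-slice stacks
# as channels) or NULL when the modality is absent. Returns the logits
# node, the tape, and the parameter leaves for gradient collection.
.forwardFCNN <- function(net, xT1 = NULL, xT2 = NULL, nativeRes,
                         training = FALSE, jitter = 1, state = NULL) {
  cfg <- net@cfg
  if (is.null(state)) state <- local({ e <- new.env(); e$stats <- net@bnStats; e })
  tape <- .tapeNew()
  lv <- lapply(net@params, function(p) .tapeLeaf(tape, p))

  if (cfg$hetero_modal) {
    if (is.null(xT1) && is.null(xT2))
      .stopf("inputError", "at least one modality required")
    f1 <- if (!is.null(xT1))
      .cdbForward(tape, .tapeLeaf(tape, xT1), "t1", lv, state, cfg, TRUE,
                  training) else NULL
    f2 <- if (!is.null(xT2))
      .cdbForward(tape, .tapeLeaf(tape, xT2), "t2", lv, state, cfg, TRUE,
                  training) else NULL
    fused <- .opFuse(tape, f1, f2, lv[["fuse.w1"]], lv[["fuse.w2"]])
  } else {
    x <- if (is.null(xT1)) xT2 else xT1
    if (is.null(x)) .stopf("inputError", "input volume required")
    fused <- .cdbForward(tape, .tapeLeaf(tape, x), "inp", lv, state, cfg,
                         TRUE, training)
  }

  nativeSize <- dim(fused$value)[1:2]
  baseSize <- .rnOutSize(nativeSize, nativeRes, cfg$base_resolution, jitter)
  xb <- .opResize(tape, fused, baseSize)

  e2 <- .cdbForward(tape, xb, "enc2", lv, state, cfg, TRUE, training)
  p1 <- .opMaxPool(tape, e2)
  e3 <- .cdbForward(tape, p1$node, "enc3", lv, state, cfg, FALSE, training)
  p2 <- .opMaxPool(tape, e3)
  e4 <- .cdbForward(tape, p2$node, "enc4", lv, state, cfg, FALSE, training)
  p3 <- .opMaxPool(tape, e4)
  e5 <- .cdbForward(tape, p3$node, "enc5", lv, state, cfg, FALSE, training)
  p4 <- .opMaxPool(tape, e5)
  bo <- .cdbForward(tape, p4$node, "bott", lv, state, cfg, FALSE, training)

  u4 <- .opUnpool(tape, bo, p4$idx, p4$inSize)
  d5 <- .cdbForward(tape, .opMaxout(tape, u4, e5), "dec5", lv, state, cfg,
                    FALSE, training)
  u3 <- .opUnpool(tape, d5, p3$idx, p3$inSize)
  d4 <- .cdbForward(tape, .opMaxout(tape, u3, e4), "dec4", lv, state, cfg,
                    FALSE, training)
  u2 <- .opUnpool(tape, d4, p2$idx, p2$inSize)
  d3 <- .cdbForward(tape, .opMaxout(tape, u2, e3), "dec3", lv, state, cfg,
                    FALSE, training)
  u1 <- .opUnpool(tape, d3, p1$idx, p1$inSize)
  d2 <- .cdbForward(tape, .opMaxout(tape, u1, e2), "dec2", lv, state, cfg,
                    FALSE, training)

  up <- .opResize(tape, d2, nativeSize)
  d1 <- .cdbForward(tape, .opConcatChannels(tape, up, fused), "dec1", lv,
                    state, cfg, FALSE, training)
  logits <- .opConv2d(tape, d1, lv[["cls.w"]], lv[["cls.b"]])
  list(logits = logits, tape = tape, leaves = lv, state = state)
}

#' Run a forward pass on raw stack arrays
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no
#' augmentation); returns class logits at the native in-plane grid.
#'
#' @param net an [HMVINN-class].
#' @param xT1,xT2 (H,W,S,N) stack arrays or `NULL` for an absent modality.
#' @param nativeRes in-plane resolution in mm.
#' @return (H,W,n_classes,N) logits array.
#' @export
forwardLogits <- function(net, xT1 = NULL, xT2 = NULL, nativeRes) {
  .forwardFCNN(net, xT1, xT2, nativeRes, training = FALSE)$logits$value
}

# ---- checkpoints ---------------------------------------------------------

#' Save / load network checkpoints
#'
#' A checkpoint stores the weights, running batch-norm moments, the
#' configuration, the plane tag and the lookup-table fingerprint; loading
#' refuses a checkpoint whose configuration or table fingerprint does not
#' match the requested ones.
#'
#' @param net an [HMVINN-class].
#' @param path file path.
#' @export
saveCheckpoint <- function(net, path) {
  saveRDS(list(format = "hyposeg-ckpt-1", cfg = net@cfg, params = net@params,
               bnStats = net@bnStats, plane = net@plane,
               lutHash = net@lutHash, epochsTrained = net@epochsTrained),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @param lut optional [LabelLookup-class]; when given, the stored
#'   fingerprint must match.
#' @param plane optional plane the caller expects.
#' @export
loadCheckpoint <- function(path, lut = NULL, plane = NULL) {
  if (!file.exists(path)) .stopf("ioError", "checkpoint not found: %s", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "hyposeg-ckpt-1"))
    .stopf("checkpointError", "not a network checkpoint: %s", path)
  if (!is.null(plane) && !identical(ck$plane, plane))
    .stopf("checkpointError", "checkpoint is for the %s plane, expected %s",
           ck$plane, plane)
  if (!is.null(lut)) {
    expect <- if (ck$plane == "sagittal")
      .lutFingerprint(mergeLateralLabels(lut)$merged)
    else .lutFingerprint(lut)
    if (!identical(ck$lutHash, expect) &&
        !identical(ck$lutHash, .lutFingerprint(lut)))
      .stopf("checkpointError", "lookup-table fingerprint mismatch")
  }
  new("HMVINN", cfg = ck$cfg, params = ck$params, bnStats = ck$bnStats,
      plane = ck$plane, lutHash = ck$lutHash,
      epochsTrained = as.integer(ck$epochsTrained))
}
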