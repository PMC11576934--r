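#' Training configuration
#'
#' Defaults follow the published training recipe: 100 epochs, batch size
#' 16, AdamW with weight decay 1e-4, learning rate 0.05 dropped to 0.005
#' after 70 epochs, modality dropout starting after 10 warm-up epochs,
#' affine augmentation (translation -15..15 mm, rotation -10..10 deg,
#' uniform scaling 0.85..1.15), bias-field coefficients -0.5..0.5, and
#' internal scale augmentation of the feature maps (multiplicative jitter
#' 0.85..1.15 on the resolution-normalization factor, sampled per batch).
#'
#' @param epochs,batch_size optimization schedule.
#' @param lr_initial,lr_late,lr_switch_epoch step learning-rate schedule:
#'   `lr_initial` through `lr_switch_epoch`, `lr_late` afterwards.
#' @param weight_decay decoupled AdamW weight decay.
#' @param modality_dropout_start_epoch first epoch with modality dropout.
#' @param affine_translation_mm,affine_rotation_deg,affine_scale spatial
#'   augmentation ranges.
#' @param bias_coeff_range bias-field polynomial coefficient range.
#' @param internal_scale_range per-batch jitter range of the internal
#'   resolution-normalization scale.
#' @param external_scale_range resolution range (mm) for external scale
#'   augmentation, or `NULL` to disable.
#' @param augment master switch for spatial/intensity augmentation.
#' @param seed master seed; one derived stream per randomness concern.
#' @return validated config list.
#' @export
trainConfig <- function(epochs = 100L, batch_size = 16L, lr_initial = 0.05,
                        lr_late = 0.005, lr_switch_epoch = 70L,
                        weight_decay = 1e-4,
                        modality_dropout_start_epoch = 10L,
                        affine_translation_mm = c(-15, 15),
                        affine_rotation_deg = c(-10, 10),
                        affine_scale = c(0.85, 1.15),
                        bias_coeff_range = c(-0.5, 0.5),
                        internal_scale_range = c(0.85, 1.15),
                        external_scale_range = NULL,
                        augment = TRUE, seed = 1L) {
  if (!(lr_late > 0 && lr_late < lr_initial))
    .stopf("configError", "need 0 < lr_late < lr_initial")
  if (lr_switch_epoch >= epochs + 1L && epochs > 0L) {
    # permissible: switch simply never triggers
  }
  ordered <- function(r) length(r) == 2L && r[1] <= r[2]
  if (!all(vapply(list(affine_translation_mm, affine_rotation_deg,
                       affine_scale, bias_coeff_range,
                       internal_scale_range), ordered, TRUE)))
    .stopf("configError", "augmentation ranges must be ordered pairs")
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr_initial = lr_initial, lr_late = lr_late,
       lr_switch_epoch = as.integer(lr_switch_epoch),
       weight_decay = weight_decay,
       modality_dropout_start_epoch = as.integer(modality_dropout_start_epoch),
       affine_translation_mm = affine_translation_mm,
       affine_rotation_deg = affine_rotation_deg,
       affine_scale = affine_scale, bias_coeff_range = bias_coeff_range,
       internal_scale_range = internal_scale_range,
       external_scale_range = external_scale_range,
       augment = isTRUE(augment), seed = as.integer(seed))
}

#' Learning rate at a given epoch
#'
#' @param epoch 1-based epoch.
#' @param cfg a [trainConfig()].
#' @return numeric learning rate.
#' @export
learningRateAt <- function(epoch, cfg) {
  if (epoch > cfg$lr_switch_epoch) cfg$lr_late else cfg$lr_initial
}

# ---- AdamW ---------------------------------------------------------------

.adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamwStep <- function(params, grads, st, lr, wd, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next # branch not exercised this step
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (upd + wd * params[[nm]])
  }
  list(params = params, state = st)
}

# ---- training loop -------------------------------------------------------

.classIndex <- function(labels, lutIds) {
  idx <- match(as.integer(labels), c(0L, lutIds))
  if (anyNA(idx)) .stopf("labelError", "label outside the lookup table")
  idx
}

#' Label histogram of a phantom dataset
#'
#' @param dataset list of samples with a `labels` volume.
#' @param lut a [LabelLookup-class].
#' @return named voxel counts (background `"0"` first).
#' @export
datasetLabelHistogram <- function(dataset, lut) {
  ids <- c(0L, lutTable(lut)$id)
  h <- setNames(numeric(length(ids)), ids)
  for (s in dataset) {
    t <- table(factor(as.integer(volData(s$labels)), levels = ids))
    h <- h + as.numeric(t)
  }
  h
}

# per-plane training tensors for one (possibly augmented) sample
.sampleToPlane <- function(s, plane, thickness, mapping = NULL) {
  ax <- .checkPlane(plane)
  vols <- list(t1 = s$t1, t2 = s$t2)
  stacks <- extractSliceStacks(vols, plane, thickness)
  lab <- volData(s$labels)
  if (!is.null(mapping)) {
    la <- lab
    for (id in names(mapping)) la[lab == as.integer(id)] <- mapping[[id]]
    lab <- la
  }
  labPerm <- aperm(lab, c(ax, .inPlaneAxes(plane)))
  res <- stacks[[1]]$inPlaneRes
  list(stacks = stacks, labels = labPerm, nativeRes = mean(res))
}

.stacksToBatch <- function(stacks, sel, what) {
  sl <- lapply(stacks[sel], function(st) aperm(st[[what]], c(2, 3, 1)))
  d <- dim(sl[[1]])
  array(unlist(sl), c(d, length(sel)))
}

#' Train a network on a phantom dataset
#'
#' Runs the full optimization loop: per-example affine, bias-field and
#' (optional) external-scale augmentation, per-example modality dropout
#' after the warm-up epochs, per-batch internal scale jitter of the
#' resolution-normalization, median-frequency-weighted cross-entropy plus
#' soft-Dice loss, and AdamW with the step learning-rate schedule. Fully
#' deterministic given the seed and dataset.
#'
#' @param net an [HMVINN-class] (its plane decides the slicing axis).
#' @param dataset list of samples, each `list(t1=, t2=, labels=)` of
#'   conformed [BrainVolume-class] objects.
#' @param cfg a [trainConfig()].
#' @param lut the [LabelLookup-class] the labels follow (the full table;
#'   sagittal networks merge internally).
#' @return list with `net` (trained) and `history` (per-epoch data.frame:
#'   epoch, loss, lr, mode counts).
#' @export
trainNetwork <- function(net, dataset, cfg, lut) {
  if (length(dataset) == 0L) .stopf("inputError", "empty dataset")
  plane <- net@plane
  mapping <- NULL
  lutIds <- lutTable(lut)$id
  if (plane == "sagittal") {
    mg <- mergeLateralLabels(lut)
    mapping <- mg$mapping
    lutIds <- lutTable(mg$merged)$id
  }
  nC <- net@cfg$n_classes
  if (nC != length(lutIds) + 1L)
    .stopf("configError",
           "network has %d classes but the %s lookup table implies %d",
           nC, plane, length(lutIds) + 1L)

  hist0 <- datasetLabelHistogram(dataset, lut)
  if (!is.null(mapping)) { # fold lateral counts together
    h <- setNames(numeric(length(lutIds) + 1L), c("0", lutIds))
    for (nm in names(hist0)) {
      tgt <- if (nm == "0") "0" else as.character(mapping[[nm]])
      h[tgt] <- h[tgt] + hist0[[nm]]
    }
    hist0 <- h
  }
  cw <- medianFrequencyWeights(hist0)

  params <- net@params
  opt <- .adamwInit(params)
  state <- local({ e <- new.env(); e$stats <- net@bnStats; e })
  history <- NULL
  epoch0 <- net@epochsTrained

  for (ep in seq_len(cfg$epochs)) {
    epoch <- epoch0 + ep
    lr <- learningRateAt(epoch, cfg)

    # augment each sample once per epoch, then slice
    planeData <- lapply(seq_along(dataset), function(i) {
      s <- dataset[[i]]
      if (cfg$augment) {
        vols <- augmentAffine(list(t1 = s$t1, t2 = s$t2, labels = s$labels),
                              cfg$affine_translation_mm,
                              cfg$affine_rotation_deg, cfg$affine_scale,
                              seed = .deriveSeed(cfg$seed,
                                                 sprintf("aff.%d.%d", epoch, i)))
        vols$t1 <- augmentBiasField(vols$t1, cfg$bias_coeff_range,
                                    seed = .deriveSeed(cfg$seed,
                                                       sprintf("bias1.%d.%d", epoch, i)))
        vols$t2 <- augmentBiasField(vols$t2, cfg$bias_coeff_range,
                                    seed = .deriveSeed(cfg$seed,
                                                       sprintf("bias2.%d.%d", epoch, i)))
        if (!is.null(cfg$external_scale_range))
          vols <- externalScaleAugment(vols, cfg$external_scale_range,
                                       seed = .deriveSeed(cfg$seed,
                                                          sprintf("exsa.%d.%d", epoch, i)))
        s <- list(t1 = vols$t1, t2 = vols$t2, labels = vols$labels)
      }
      .sampleToPlane(s, plane, net@cfg$stack_thickness, mapping)
    })

    index <- do.call(rbind, lapply(seq_along(planeData), function(i)
      cbind(i, seq_along(planeData[[i]]$stacks))))
    ord <- .withSeed(.deriveSeed(cfg$seed, sprintf("order.%d", epoch)),
                     sample.int(nrow(index)))
    index <- index[ord, , drop = FALSE]
    modes <- .withSeed(.deriveSeed(cfg$seed, sprintf("mode.%d", epoch)),
                       sampleModalityMode(epoch, nrow(index),
                                          cfg$modality_dropout_start_epoch + 1L))
    nBatches <- ceiling(nrow(index) / cfg$batch_size)
    jitters <- .withSeed(.deriveSeed(cfg$seed, sprintf("jit.%d", epoch)),
                         runif(nBatches, cfg$internal_scale_range[1],
                               cfg$internal_scale_range[2]))

    epLoss <- 0
    nSeen <- 0
    modeCount <- c(t1t2 = 0L, t1_only = 0L, t2_only = 0L)
    for (b in seq_len(nBatches)) {
      rows <- seq((b - 1L) * cfg$batch_size + 1L,
                  min(b * cfg$batch_size, nrow(index)))
      bmodes <- modes[rows]
      grads <- list()
      bloss <- 0
      for (md in unique(bmodes)) {
        sub <- rows[bmodes == md]
        modeCount[md] <- modeCount[md] + length(sub)
        # group by source sample so shapes (and native res) match
        bySample <- split(sub, index[sub, 1])
        for (si in names(bySample)) {
          rr <- bySample[[si]]
          pd <- planeData[[as.integer(si)]]
          sel <- index[rr, 2]
          xT1 <- if (md != "t2_only") .stacksToBatch(pd$stacks, sel, "t1")
          xT2 <- if (md != "t1_only") .stacksToBatch(pd$stacks, sel, "t2")
          target <- array(.classIndex(pd$labels[sel, , , drop = FALSE], lutIds),
                          dim(pd$labels[sel, , , drop = FALSE]))
          target <- aperm(target, c(2, 3, 1))
          fw <- .forwardFCNN(netWith(net, params), xT1, xT2, pd$nativeRes,
                             training = TRUE, jitter = jitters[b],
                             state = state)
          ls <- combinedLoss(fw$logits$value, target, cw)
          frac <- length(rr) / length(rows)
          .tapeBackward(fw$tape, fw$logits, ls$grad * frac)
          for (nm in names(fw$leaves)) {
            g <- fw$leaves[[nm]]$grad
            if (is.null(g)) next
            grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
          }
          bloss <- bloss + ls$loss * frac
        }
      }
      stp <- .adamwStep(params, grads, opt, lr, cfg$weight_decay)
      params <- stp$params
      opt <- stp$state
      epLoss <- epLoss + bloss * length(rows)
      nSeen <- nSeen + length(rows)
    }

    history <- rbind(history, data.frame(
      epoch = epoch, loss = epLoss / nSeen, lr = lr,
      n_t1t2 = modeCount[["t1t2"]], n_t1 = modeCount[["t1_only"]],
      n_t2 = modeCount[["t2_only"]]))
  }

  out <- new("HMVINN", cfg = net@cfg, params = params,
             bnStats = state$stats, plane = plane, lutHash = net@lutHash,
             epochsTrained = epoch0 + cfg$epochs)
  rownames(history) <- NULL
  list(net = out, history = history)
}

# shallow copy of a network with replaced parameters
netWith <- function(net, params) {
  net@params <- params
  net
}
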