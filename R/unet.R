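# Compact 2D U-Net segmentation stage, implemented in base R matrix algebra
# (im2col convolutions on BLAS, hand-written backpropagation, Adam). Three
# resolution levels, one 3x3 convolution per level, nearest-neighbour
# upsampling with skip concatenation, and a 1x1 output head. Inputs are
# full-resolution slices with two normalized coordinate channels appended,
# so classes that differ only by position (tibial vs femoral tissue) remain
# separable at small receptive fields.
#
# The loss is weighted cross-entropy with equal weights for all foreground
# classes and the background weight set to half the foreground weight;
# optimization is Adam (initial learning rate 0.01, moment decays
# 0.9/0.999).

#' TrainConfig: U-Net training configuration
#'
#' @slot foregroundWeight Loss weight for every foreground class.
#' @slot backgroundWeight Loss weight for background; \code{NA} means half
#'   the foreground weight (the default convention).
#' @slot learningRate Adam initial learning rate.
#' @slot lrDecay Multiplicative learning-rate decay per epoch (exponential
#'   schedule; 1 keeps the rate constant).
#' @slot beta1,beta2 Adam exponential decay rates for the first/second
#'   moment estimates.
#' @slot epochs Training epochs.
#' @slot batchSize Slices per optimizer step.
#' @slot widths Channel widths of the three levels.
#' @slot seed Integer seed (reproducible parameters on the same BLAS).
#' @export
setClass("TrainConfig",
  representation(foregroundWeight = "numeric", backgroundWeight = "numeric",
                 learningRate = "numeric", lrDecay = "numeric",
                 beta1 = "numeric",
                 beta2 = "numeric", epochs = "numeric", batchSize = "numeric",
                 widths = "numeric", seed = "numeric"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learning rate must be > 0")
  if (object@lrDecay <= 0 || object@lrDecay > 1)
    msg <- c(msg, "lrDecay must be in (0, 1]")
  if (object@foregroundWeight <= 0)
    msg <- c(msg, "foreground weight must be > 0")
  if (!is.na(object@backgroundWeight) && object@backgroundWeight <= 0)
    msg <- c(msg, "background weight must be > 0")
  if (object@epochs < 0) msg <- c(msg, "epochs must be >= 0")
  if (length(object@widths) != 3) msg <- c(msg, "widths must have length 3")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#'
#' @param foregroundWeight,backgroundWeight Loss weights; background
#'   defaults to half the foreground weight.
#' @param learningRate,beta1,beta2 Adam hyperparameters.
#' @param lrDecay Per-epoch exponential learning-rate decay factor.
#' @param epochs,batchSize Training schedule.
#' @param widths Channel widths per level.
#' @param seed Integer seed.
#' @return A validated \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(foregroundWeight = 1, backgroundWeight = NA_real_,
                        learningRate = 0.01, lrDecay = 0.85,
                        beta1 = 0.9, beta2 = 0.999,
                        epochs = 20L, batchSize = 8L, widths = c(8, 16, 32),
                        seed = 1) {
  new("TrainConfig", foregroundWeight = foregroundWeight,
      backgroundWeight = backgroundWeight, learningRate = learningRate,
      lrDecay = lrDecay,
      beta1 = beta1, beta2 = beta2, epochs = epochs, batchSize = batchSize,
      widths = widths, seed = seed)
}

setMethod("show", "TrainConfig", function(object) {
  w <- lossWeights(object, c("background", "fg"))
  cat("TrainConfig: Adam lr ", object@learningRate, " (beta ",
      object@beta1, "/", object@beta2, "), ", object@epochs,
      " epoch(s), weights fg ", object@foregroundWeight, " / bg ",
      w["background"], "\n", sep = "")
  invisible(object)
})

#' Per-class loss weights of a training configuration
#'
#' Equal weights for all foreground classes; the background weight defaults
#' to half the foreground weight.
#'
#' @param config A \linkS4class{TrainConfig} or \linkS4class{SegModel}.
#' @param classes Class names, background first.
#' @return Named numeric vector of weights.
#' @export
lossWeights <- function(config, classes) {
  if (is(config, "SegModel")) {
    classes <- config@classes
    config <- do.call(trainConfig, config@config)
  }
  wf <- config@foregroundWeight
  wb <- if (is.na(config@backgroundWeight)) wf / 2 else config@backgroundWeight
  stats::setNames(c(wb, rep(wf, length(classes) - 1L)), classes)
}

## --- class mappings per segmentation target ------------------------------

targetClasses <- function(target) {
  switch(target,
    "cartilage" = c("background", "tibial_cartilage", "femoral_cartilage"),
    "bone-area" = c("background", "tibial_boneArea", "femoral_boneArea"),
    stop("unknown target: ", target))
}

## map dictionary label ids to 0-based class ids for a target
labelsToClasses <- function(labels, target, dict = cartLabels()) {
  cls <- array(0L, dim(labels))
  if (target == "cartilage") {
    cls[labels %in% dict[c("MT", "LT")]] <- 1L
    cls[labels %in% dict[c("cMF", "cLF")]] <- 2L
  } else {
    cls[labels %in% dict[c("tAB_MT", "tAB_LT")]] <- 1L
    cls[labels %in% dict[c("tAB_cMF", "tAB_cLF")]] <- 2L
  }
  cls
}

## --- im2col machinery -----------------------------------------------------

.im2colCache <- new.env(parent = emptyenv())

im2colIndex <- function(H, W) {
  key <- paste(H, W, sep = "x")
  if (!is.null(.im2colCache[[key]])) return(.im2colCache[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  ii <- rep(seq_len(H), W)
  jj <- rep(seq_len(W), each = H)
  center <- (jj) * Hp + ii + 1L   # (i+1) + (j+1-1)*Hp
  offs <- expand.grid(di = -1:1, dj = -1:1)
  idx <- matrix(0L, H * W, 9L)
  for (k in 1:9)
    idx[, k] <- center + offs$di[k] + offs$dj[k] * Hp
  out <- list(idx = idx, center = center, Hp = Hp, Wp = Wp)
  .im2colCache[[key]] <- out
  out
}

## X: (H*W) x C -> (H*W) x (9C) with zero padding
im2col <- function(X, H, W) {
  m <- im2colIndex(H, W)
  C <- ncol(X)
  Xp <- matrix(0, m$Hp * m$Wp, C)
  Xp[m$center, ] <- X
  out <- matrix(0, H * W, 9L * C)
  for (k in 1:9)
    out[, ((k - 1L) * C + 1L):(k * C)] <- Xp[m$idx[, k], , drop = FALSE]
  out
}

## scatter-add transpose of im2col: dX2 (HW x 9C) -> dX (HW x C)
col2im <- function(dX2, H, W, C) {
  m <- im2colIndex(H, W)
  dXp <- matrix(0, m$Hp * m$Wp, C)
  for (k in 1:9) {
    blk <- dX2[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
    dXp[m$idx[, k], ] <- dXp[m$idx[, k], , drop = FALSE] + blk
  }
  dXp[m$center, , drop = FALSE]
}

## --- layers ---------------------------------------------------------------

poolForward <- function(X, H, W) {
  C <- ncol(X)
  a <- array(X, c(H, W, C))
  io <- seq(1, H, 2); jo <- seq(1, W, 2)
  s1 <- a[io, jo, , drop = FALSE];  s2 <- a[io + 1, jo, , drop = FALSE]
  s3 <- a[io, jo + 1, , drop = FALSE]; s4 <- a[io + 1, jo + 1, , drop = FALSE]
  p <- pmax(s1, s2, s3, s4)
  which4 <- array(1L, dim(p))
  which4[p == s2 & s2 > s1] <- 2L
  which4[p == s3 & s3 > pmax(s1, s2)] <- 3L
  which4[p == s4 & s4 > pmax(s1, s2, s3)] <- 4L
  list(out = matrix(p, (H / 2) * (W / 2), C), which = which4)
}

poolBackward <- function(dOut, which4, H, W) {
  C <- ncol(dOut)
  h2 <- H / 2; w2 <- W / 2
  dp <- array(dOut, c(h2, w2, C))
  da <- array(0, c(H, W, C))
  io <- seq(1, H, 2); jo <- seq(1, W, 2)
  for (q in 1:4) {
    sel <- which4 == q
    g <- array(0, dim(dp)); g[sel] <- dp[sel]
    di <- if (q %in% c(2, 4)) 1 else 0
    dj <- if (q %in% c(3, 4)) 1 else 0
    da[io + di, jo + dj, ] <- da[io + di, jo + dj, , drop = FALSE] + g
  }
  matrix(da, H * W, C)
}

upForward <- function(X, H, W) {   # input H x W grid -> 2H x 2W nearest
  C <- ncol(X)
  a <- array(X, c(H, W, C))
  big <- a[rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), ,
           drop = FALSE]
  matrix(big, 4 * H * W, C)
}

upBackward <- function(dOut, H, W) {  # sum the 2x2 blocks
  C <- ncol(dOut)
  a <- array(dOut, c(2 * H, 2 * W, C))
  io <- seq(1, 2 * H, 2); jo <- seq(1, 2 * W, 2)
  s <- a[io, jo, , drop = FALSE] + a[io + 1, jo, , drop = FALSE] +
    a[io, jo + 1, , drop = FALSE] + a[io + 1, jo + 1, , drop = FALSE]
  matrix(s, H * W, C)
}

## --- network --------------------------------------------------------------

initUnet <- function(cin, widths, nClasses, seed) {
  withSeed(seed, {
    he <- function(fanIn, nOut) {
      matrix(stats::rnorm(fanIn * nOut, 0, sqrt(2 / fanIn)), fanIn, nOut)
    }
    w1 <- widths[1]; w2 <- widths[2]; w3 <- widths[3]
    list(
      W1 = he(9 * cin, w1),      b1 = numeric(w1),
      W2 = he(9 * w1, w2),       b2 = numeric(w2),
      W3 = he(9 * w2, w3),       b3 = numeric(w3),
      W4 = he(9 * (w3 + w2), w2), b4 = numeric(w2),
      W5 = he(9 * (w2 + w1), w1), b5 = numeric(w1),
      W6 = he(w1, nClasses),     b6 = numeric(nClasses))
  })
}

convF <- function(X, H, W, Wm, b) {
  X2 <- im2col(X, H, W)
  list(out = sweep(X2 %*% Wm, 2, b, "+"), X2 = X2)
}

## leaky ReLU (slope 0.01) avoids dead units at aggressive learning rates
lrelu <- function(x) pmax(x, 0) + 0.01 * pmin(x, 0)
lreluGradMask <- function(g, act) {
  g[act <= 0] <- 0.01 * g[act <= 0]
  g
}

unetForward <- function(params, X, H, W) {
  cc <- list(H = H, W = W)
  c1 <- convF(X, H, W, params$W1, params$b1)
  e1 <- lrelu(c1$out)
  p1 <- poolForward(e1, H, W)
  H2 <- H / 2; W2 <- W / 2
  c2 <- convF(p1$out, H2, W2, params$W2, params$b2)
  e2 <- lrelu(c2$out)
  p2 <- poolForward(e2, H2, W2)
  H4 <- H / 4; W4 <- W / 4
  c3 <- convF(p2$out, H4, W4, params$W3, params$b3)
  bt <- lrelu(c3$out)
  u2 <- upForward(bt, H4, W4)
  cat2 <- cbind(u2, e2)
  c4 <- convF(cat2, H2, W2, params$W4, params$b4)
  d2 <- lrelu(c4$out)
  u1 <- upForward(d2, H2, W2)
  cat1 <- cbind(u1, e1)
  c5 <- convF(cat1, H, W, params$W5, params$b5)
  d1 <- lrelu(c5$out)
  logits <- sweep(d1 %*% params$W6, 2, params$b6, "+")
  list(logits = logits,
       cache = list(X = X, c1 = c1, e1 = e1, p1 = p1, c2 = c2, e2 = e2,
                    p2 = p2, c3 = c3, bt = bt, cat2 = cat2, c4 = c4,
                    d2 = d2, cat1 = cat1, c5 = c5, d1 = d1,
                    H = H, W = W))
}

unetBackward <- function(params, fw, dLogits) {
  cc <- fw$cache
  H <- cc$H; W <- cc$W; H2 <- H / 2; W2 <- W / 2; H4 <- H / 4; W4 <- W / 4
  g <- list()
  g$W6 <- crossprod(cc$d1, dLogits); g$b6 <- colSums(dLogits)
  dd1 <- tcrossprod(dLogits, params$W6)
  dd1 <- lreluGradMask(dd1, cc$d1)
  g$W5 <- crossprod(im2col(cc$cat1, H, W), dd1); g$b5 <- colSums(dd1)
  dcat1 <- col2im(dd1 %*% t(params$W5), H, W, ncol(cc$cat1))
  w2w <- ncol(cc$d2)   # width of decoder level-2 output feeding u1
  du1 <- dcat1[, seq_len(w2w), drop = FALSE]
  de1 <- dcat1[, (w2w + 1L):ncol(dcat1), drop = FALSE]
  dd2 <- upBackward(du1, H2, W2)
  dd2 <- lreluGradMask(dd2, cc$d2)
  g$W4 <- crossprod(im2col(cc$cat2, H2, W2), dd2); g$b4 <- colSums(dd2)
  dcat2 <- col2im(dd2 %*% t(params$W4), H2, W2, ncol(cc$cat2))
  w3w <- ncol(cc$bt)
  du2 <- dcat2[, seq_len(w3w), drop = FALSE]
  de2b <- dcat2[, (w3w + 1L):ncol(dcat2), drop = FALSE]
  dbt <- upBackward(du2, H4, W4)
  dbt <- lreluGradMask(dbt, cc$bt)
  g$W3 <- crossprod(cc$c3$X2, dbt); g$b3 <- colSums(dbt)
  dp2 <- col2im(dbt %*% t(params$W3), H4, W4, ncol(cc$p2$out))
  de2 <- poolBackward(dp2, cc$p2$which, H2, W2) + de2b
  de2 <- lreluGradMask(de2, cc$e2)
  g$W2 <- crossprod(cc$c2$X2, de2); g$b2 <- colSums(de2)
  dp1 <- col2im(de2 %*% t(params$W2), H2, W2, ncol(cc$p1$out))
  de1b <- poolBackward(dp1, cc$p1$which, H, W) + de1
  de1b <- lreluGradMask(de1b, cc$e1)
  g$W1 <- crossprod(cc$c1$X2, de1b); g$b1 <- colSums(de1b)
  g
}

softmaxRows <- function(logits) {
  m <- logits - apply(logits, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

weightedCELoss <- function(logits, target, weights) {
  ## target: 0-based class per pixel
  p <- softmaxRows(logits)
  n <- nrow(logits)
  wpix <- weights[target + 1L]
  ip <- p[cbind(seq_len(n), target + 1L)]
  loss <- -sum(wpix * log(pmax(ip, 1e-12))) / sum(wpix)
  dLogits <- p
  dLogits[cbind(seq_len(n), target + 1L)] <-
    dLogits[cbind(seq_len(n), target + 1L)] - 1
  dLogits <- dLogits * wpix / sum(wpix)
  list(loss = loss, dLogits = dLogits)
}

padTo4 <- function(mat, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  H4 <- ceiling(H / 4) * 4; W4 <- ceiling(W / 4) * 4
  if (H4 == H && W4 == W) return(list(m = mat, H = H, W = W))
  out <- matrix(fill, H4, W4)
  out[seq_len(H), seq_len(W)] <- mat
  list(m = out, H = H, W = W)
}

## slice image -> input matrix (HW x 3): intensity + normalized coords
sliceInput <- function(img) {
  H <- nrow(img); W <- ncol(img)
  cbind(as.vector(img) / 255,
        rep(seq_len(H) / H, W),
        rep(seq_len(W) / W, each = H))
}

#' Train a compact 2D U-Net
#'
#' Trains on full-resolution 2D slices with weighted cross-entropy (equal
#' foreground weights, background at half) and Adam (learning rate 0.01,
#' moment decays 0.9/0.999). With 0 epochs the randomly initialized model is
#' returned and prediction still works.
#'
#' @param slicePairs List of \code{list(image = , labels = )} matrices; the
#'   labels use the mask dictionary (\code{\link{cartLabels}}).
#' @param config A \linkS4class{TrainConfig}.
#' @param target "cartilage" or "bone-area".
#' @param protocol Protocol identity recorded in the model.
#' @return A \linkS4class{SegModel} whose \code{params$history} records the
#'   mean training loss per epoch.
#' @export
trainUnet <- function(slicePairs, config = trainConfig(),
                      target = "cartilage", protocol = "sagittal-DESS") {
  validObject(config)
  if (!length(slicePairs)) stop("empty training set")
  dict <- cartLabels()
  for (sp in slicePairs) {
    if (!is.matrix(sp$image) || !is.matrix(sp$labels) ||
        !identical(dim(sp$image), dim(sp$labels)))
      stop("each slice pair needs matching image and labels matrices")
    bad <- setdiff(unique(as.vector(sp$labels)), dict)
    if (length(bad))
      stop("label id(s) outside dictionary: ", paste(bad, collapse = ", "))
  }
  classes <- targetClasses(target)
  nC <- length(classes)
  weights <- lossWeights(config, classes)
  params <- initUnet(3L, config@widths, nC, config@seed)
  ## Adam state
  mState <- lapply(params, function(p) p * 0)
  vState <- lapply(params, function(p) p * 0)
  tStep <- 0L
  history <- numeric(0)
  prep <- lapply(slicePairs, function(sp) {
    pi <- padTo4(sp$image)
    pl <- padTo4(labelsToClasses(sp$labels, target, dict))
    list(X = sliceInput(pi$m), y = as.integer(as.vector(pl$m)),
         H = nrow(pi$m), W = ncol(pi$m))
  })
  nS <- length(prep)
  bs <- max(1L, min(config@batchSize, nS))
  epochs <- as.integer(config@epochs)
  if (epochs > 0) withSeed(childSeed(config@seed, 1), {
    for (ep in seq_len(epochs)) {
      lrEpoch <- config@learningRate * config@lrDecay^(ep - 1)
      ord <- sample.int(nS)
      epLoss <- 0
      b0 <- 1L
      while (b0 <= nS) {
        bIdx <- ord[b0:min(nS, b0 + bs - 1L)]
        grads <- NULL
        bLoss <- 0
        for (si in bIdx) {
          s <- prep[[si]]
          fw <- unetForward(params, s$X, s$H, s$W)
          ls <- weightedCELoss(fw$logits, s$y, weights)
          bLoss <- bLoss + ls$loss
          g <- unetBackward(params, fw, ls$dLogits)
          grads <- if (is.null(grads)) g
                   else mapply(`+`, grads, g, SIMPLIFY = FALSE)
        }
        grads <- lapply(grads, function(g) g / length(bIdx))
        tStep <- tStep + 1L
        for (nm in names(params)) {
          mState[[nm]] <- config@beta1 * mState[[nm]] +
            (1 - config@beta1) * grads[[nm]]
          vState[[nm]] <- config@beta2 * vState[[nm]] +
            (1 - config@beta2) * grads[[nm]]^2
          mHat <- mState[[nm]] / (1 - config@beta1^tStep)
          vHat <- vState[[nm]] / (1 - config@beta2^tStep)
          params[[nm]] <- params[[nm]] -
            lrEpoch * mHat / (sqrt(vHat) + 1e-8)
        }
        epLoss <- epLoss + bLoss
        b0 <- b0 + bs
      }
      history <- c(history, epLoss / nS)
    }
  })
  cfg <- list(foregroundWeight = config@foregroundWeight,
              backgroundWeight = config@backgroundWeight,
              learningRate = config@learningRate, lrDecay = config@lrDecay,
              beta1 = config@beta1,
              beta2 = config@beta2, epochs = config@epochs,
              batchSize = config@batchSize, widths = config@widths,
              seed = config@seed)
  new("SegModel", params = c(params, list(history = history)),
      target = target, protocol = protocol, classes = classes,
      config = cfg, oracle = FALSE)
}

#' Ground-truth oracle segmentation model
#'
#' A model variant that bypasses inference and returns the stored
#' ground-truth mask, so the post-processing and morphometry stages can be
#' exercised independently of training.
#'
#' @param truth Ground-truth \linkS4class{LabelMask}.
#' @param target "cartilage" or "bone-area".
#' @return A \linkS4class{SegModel} with \code{oracle = TRUE}.
#' @export
oracleSegModel <- function(truth, target = "cartilage") {
  new("SegModel", params = list(truth = truth), target = target,
      protocol = protocolOf(truth), classes = targetClasses(target),
      config = list(), oracle = TRUE)
}

## slices of a volume along the protocol's acquisition axis
sliceAxis <- function(protocol) {
  if (grepl("sagittal", protocol)) 2L else 1L
}

getSlice <- function(arr, axis, j) {
  if (axis == 2L) arr[, j, ] else arr[j, , ]
}

#' Extract training slice pairs from a phantom
#'
#' Slices the phantom volume and mask along the protocol's acquisition axis
#' (sagittal: medial--lateral; coronal: anterior--posterior) and keeps
#' slices containing foreground for the given target.
#'
#' @param phantom Output of \code{\link{makePhantom}}.
#' @param target "cartilage" or "bone-area".
#' @param step Keep every \code{step}-th qualifying slice.
#' @return List of \code{list(image, labels)} matrices.
#' @export
phantomSlices <- function(phantom, target = "cartilage", step = 1L) {
  vol <- phantom$volume; mask <- phantom$mask
  ax <- sliceAxis(protocolOf(vol))
  n <- dim(voxelData(vol))[ax]
  out <- list()
  for (j in seq(1L, n, by = step)) {
    labs <- getSlice(voxelData(mask), ax, j)
    if (!any(labelsToClasses(labs, target) > 0L)) next
    out[[length(out) + 1L]] <-
      list(image = getSlice(voxelData(vol), ax, j), labels = labs)
  }
  out
}

#' Predict a label mask for a volume
#'
#' Slice-wise argmax prediction assembled into a 3D mask with the volume's
#' geometry. Ties at the argmax resolve to the lowest class id. Predicted
#' tissue classes are assigned to medial or lateral plate labels from the
#' slice (or pixel) position relative to the volume's medial--lateral
#' midline.
#'
#' @param model A \linkS4class{SegModel}.
#' @param volume A \linkS4class{VoxelVolume} of the model's protocol.
#' @return A \linkS4class{LabelMask}.
#' @export
predictMask <- function(model, volume) {
  if (!identical(protocolOf(model), protocolOf(volume)))
    stop("protocol mismatch: model is ", protocolOf(model), ", volume is ",
         protocolOf(volume))
  if (model@oracle) {
    truth <- model@params$truth
    if (!sameGeometry(truth, volume))
      stop("oracle truth does not match the volume geometry")
    return(truth)
  }
  arr <- voxelData(volume)
  d <- dim(arr)
  ax <- sliceAxis(protocolOf(volume))
  cls <- array(0L, d)
  for (j in seq_len(d[ax])) {
    img <- getSlice(arr, ax, j)
    pp <- padTo4(img)
    X <- sliceInput(pp$m)
    fw <- unetForward(model@params, X, nrow(pp$m), ncol(pp$m))
    pred <- max.col(fw$logits, ties.method = "first") - 1L
    predM <- matrix(pred, nrow(pp$m), ncol(pp$m))[seq_len(pp$H),
                                                  seq_len(pp$W)]
    if (ax == 2L) cls[, j, ] <- predM else cls[j, , ] <- predM
  }
  ## map tissue classes to plate labels by medial/lateral position
  L <- cartLabels()
  yMid <- (d[2] + 1) / 2
  medial <- array(rep(rep(seq_len(d[2]) <= yMid, each = d[1]), d[3]), d)
  lab <- array(0L, d)
  if (model@target == "cartilage") {
    lab[cls == 1L & medial] <- L["MT"]
    lab[cls == 1L & !medial] <- L["LT"]
    lab[cls == 2L & medial] <- L["cMF"]
    lab[cls == 2L & !medial] <- L["cLF"]
  } else {
    lab[cls == 1L & medial] <- L["tAB_MT"]
    lab[cls == 1L & !medial] <- L["tAB_LT"]
    lab[cls == 2L & medial] <- L["tAB_cMF"]
    lab[cls == 2L & !medial] <- L["tAB_cLF"]
  }
  new("LabelMask", data = lab, spacing = voxelSpacing(volume),
      origin = voxelOrigin(volume), protocol = protocolOf(volume),
      labels = cartLabels())
}

#' Dice similarity coefficient for one label
#'
#' 2|A intersect B| / (|A| + |B|); 1 when both masks are empty for the
#' label. Symmetric in its mask arguments.
#'
#' @param pred,truth \linkS4class{LabelMask} objects on the same grid.
#' @param label Label name or integer id.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(pred, truth, label) {
  if (!sameGeometry(pred, truth)) stop("geometry mismatch between masks")
  id <- if (is.character(label)) labelDict(truth)[label] else label
  a <- voxelData(pred) == id
  b <- voxelData(truth) == id
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Merge cartilage and bone-area predictions into one mask
#'
#' @param cartilageMask,boneMask \linkS4class{LabelMask} objects on the same
#'   grid carrying cartilage and bone-area labels respectively.
#' @return Combined \linkS4class{LabelMask} (cartilage wins on conflicts).
#' @export
combineMasks <- function(cartilageMask, boneMask) {
  if (!sameGeometry(cartilageMask, boneMask))
    stop("geometry mismatch between masks")
  L <- cartLabels()
  lab <- voxelData(boneMask)
  cl <- voxelData(cartilageMask)
  sel <- cl %in% L[platesAll()]
  lab[sel] <- cl[sel]
  out <- cartilageMask
  out@data <- lab
  out
}
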