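#' Slice classifier configuration
#'
#' The classifier maps a 3-channel 2D slice through a convolutional
#' backbone to a `featureDim`-length feature vector, appends three scaled
#' metadata values (age / 100, sex code, slice number / nSlices), and feeds
#' the concatenated vector to a fully connected head with two output nodes
#' and softmax. With the defaults (featureDim 1024, 3 metadata values) the
#' concatenated vector has 1027 entries.
#'
#' The bundled backbone `tiny_cnn` is a small three-stage convolutional
#' network (8/16/32 channels of 3x3 kernels, each stage followed by 2x2 max
#' pooling, then a fully connected map to `featureDim`); it honours the
#' same feature-vector contract as a large backbone, so the head and all
#' downstream code are backbone-agnostic.
#'
#' @param backbone "tiny_cnn" (implemented) or "inception_v4" (reserved;
#'   pretrained weights are out of scope).
#' @param featureDim backbone output length (default 1024).
#' @param inputSize square input size in pixels fed to the backbone
#'   (slices are bilinearly resized); must be divisible by 8.
#' @param metadataDim number of appended metadata values (3).
#' @param nSlices slices per subject, used to scale the slice-number input.
#' @return validated list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(backbone = c("tiny_cnn", "inception_v4"),
                             featureDim = 1024L, inputSize = 32L,
                             metadataDim = 3L, nSlices = 30L,
                             cropSize = NULL) {
  backbone <- match.arg(backbone)
  if (inputSize %% 8 != 0) stop("inputSize must be divisible by 8")
  if (featureDim < 2) stop("featureDim must be >= 2")
  cfg <- list(backbone = backbone, featureDim = as.integer(featureDim),
              inputSize = as.integer(inputSize),
              metadataDim = as.integer(metadataDim),
              nSlices = as.integer(nSlices),
              cropSize = if (is.null(cropSize)) NULL else as.integer(cropSize),
              concatDim = as.integer(featureDim + metadataDim),
              channels = c(8L, 16L, 32L))
  class(cfg) <- "ClassifierConfig"
  cfg
}

# Centre-crop (optional) and resize a native slice to the backbone input.
prepSliceImage <- function(img, config) {
  if (!is.null(config$cropSize)) {
    d <- dim(img)
    s <- min(config$cropSize, d)
    o1 <- (d[1] - s) %/% 2
    o2 <- (d[2] - s) %/% 2
    img <- img[o1 + seq_len(s), o2 + seq_len(s), drop = FALSE]
  }
  if (!all(dim(img) == c(config$inputSize, config$inputSize)))
    img <- .resizeBilinear2C(img, config$inputSize, config$inputSize)
  img
}

#' Training configuration
#'
#' Mini-batch stochastic gradient descent with Nesterov momentum, weight
#' decay 5e-5, base learning rate 0.001 decayed by 0.1 on validation-loss
#' plateaus (at most 3 decays), and early stopping when the moving average
#' of validation accuracy fails to improve by more than 5e-4 within the
#' last 5 epochs.
#'
#' @param batchSize mini-batch size.
#' @param baseLr base learning rate.
#' @param weightDecay L2 weight decay coefficient.
#' @param momentum Nesterov momentum coefficient.
#' @param lrDecayFactor multiplicative decay on plateau.
#' @param maxLrDecays maximum number of decays.
#' @param plateauTol relative validation-loss improvement below which an
#'   epoch counts toward a plateau.
#' @param plateauPatience epochs without improvement before decaying.
#' @param earlyStopDelta minimum moving-average accuracy improvement
#'   required to continue.
#' @param earlyStopWindow moving-average window (epochs).
#' @param maxEpochs epoch budget.
#' @param seed training RNG seed.
#' @return validated list of class `TrainConfig`.
#' @export
trainConfig <- function(batchSize = 64L, baseLr = 0.001, weightDecay = 5e-5,
                        momentum = 0.9, lrDecayFactor = 0.1, maxLrDecays = 3L,
                        plateauTol = 1e-4, plateauPatience = 3L,
                        earlyStopDelta = 5e-4, earlyStopWindow = 5L,
                        maxEpochs = 30L, seed = 1L) {
  if (baseLr <= 0 || batchSize < 1 || maxEpochs < 1)
    stop("rates and counts must be positive")
  if (lrDecayFactor <= 0 || lrDecayFactor >= 1)
    stop("lrDecayFactor must be in (0, 1)")
  if (weightDecay < 0 || momentum < 0 || momentum >= 1)
    stop("invalid weightDecay or momentum")
  cfg <- list(batchSize = as.integer(batchSize), baseLr = baseLr,
              weightDecay = weightDecay, momentum = momentum,
              lrDecayFactor = lrDecayFactor,
              maxLrDecays = as.integer(maxLrDecays), plateauTol = plateauTol,
              plateauPatience = as.integer(plateauPatience),
              earlyStopDelta = earlyStopDelta,
              earlyStopWindow = as.integer(earlyStopWindow),
              maxEpochs = as.integer(maxEpochs), seed = as.integer(seed))
  class(cfg) <- "TrainConfig"
  cfg
}

# Scale metadata onto the feature scale: age/100, sex in {0,1},
# slice number / nSlices.
metaScale <- function(age, sex, sliceNumber, nSlices) {
  rbind(age / 100, sex, sliceNumber / nSlices)
}

#' Initialise classifier weights
#'
#' He-style normal initialisation, deterministic under the seed.
#'
#' @param config a `ClassifierConfig`.
#' @param seed RNG seed.
#' @return named list of weight matrices and bias vectors.
#' @export
initWeights <- function(config, seed = 1L) {
  if (config$backbone != "tiny_cnn")
    stop("backbone '", config$backbone, "' is not bundled; use tiny_cnn")
  set.seed(seed)
  he <- function(nout, nin) {
    matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nrow = nout)
  }
  ch <- config$channels
  flatDim <- (config$inputSize / 8)^2 * ch[3]
  list(convW1 = he(ch[1], 3 * 9), convB1 = numeric(ch[1]),
       bnG1 = rep(1, ch[1]), bnB1 = numeric(ch[1]),
       convW2 = he(ch[2], ch[1] * 9), convB2 = numeric(ch[2]),
       bnG2 = rep(1, ch[2]), bnB2 = numeric(ch[2]),
       convW3 = he(ch[3], ch[2] * 9), convB3 = numeric(ch[3]),
       bnG3 = rep(1, ch[3]), bnB3 = numeric(ch[3]),
       fcW = he(config$featureDim, flatDim),
       fcB = numeric(config$featureDim),
       headW = he(2L, config$concatDim), headB = numeric(2L))
}

# Fresh running batch-norm statistics (per conv stage).
initBnStats <- function(config) {
  ch <- config$channels
  list(m1 = numeric(ch[1]), v1 = rep(1, ch[1]),
       m2 = numeric(ch[2]), v2 = rep(1, ch[2]),
       m3 = numeric(ch[3]), v3 = rep(1, ch[3]))
}

relu3 <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward pass over a batch. x: array (H, W, 3*B); meta: matrix (3 x B).
# bnStats carries running batch-norm statistics; training toggles batch
# vs running statistics. Batch normalisation with fused ReLU runs in
# compiled code (.bnReluFwdC / .bnReluBwdC).
forwardBatch <- function(weights, config, x, meta, bnStats = NULL,
                         training = FALSE, keepCache = FALSE) {
  if (is.null(bnStats)) bnStats <- initBnStats(config)
  ch <- config$channels
  B <- dim(x)[3] / 3L
  a1 <- .convFwdC(x, weights$convW1, weights$convB1, 3L)
  n1 <- .bnReluFwdC(a1, ch[1], weights$bnG1, weights$bnB1, bnStats$m1,
                    bnStats$v1, training)
  p1 <- .maxPoolFwdC(n1$out)
  a2 <- .convFwdC(p1$y, weights$convW2, weights$convB2, ch[1])
  n2 <- .bnReluFwdC(a2, ch[2], weights$bnG2, weights$bnB2, bnStats$m2,
                    bnStats$v2, training)
  p2 <- .maxPoolFwdC(n2$out)
  a3 <- .convFwdC(p2$y, weights$convW3, weights$convB3, ch[2])
  n3 <- .bnReluFwdC(a3, ch[3], weights$bnG3, weights$bnB3, bnStats$m3,
                    bnStats$v3, training)
  p3 <- .maxPoolFwdC(n3$out)
  flat <- p3$y
  dim(flat) <- c(length(flat) / B, B)
  f0 <- weights$fcW %*% flat + weights$fcB
  f <- relu3(f0)
  concat <- rbind(f, meta)
  z <- weights$headW %*% concat + weights$headB
  zs <- sweep(z, 2, apply(z, 2, max))
  e <- exp(zs)
  p <- sweep(e, 2, colSums(e), "/")
  out <- list(probAD = p[2, ], probs = p,
              bnStats = list(m1 = n1$rm, v1 = n1$rv, m2 = n2$rm,
                             v2 = n2$rv, m3 = n3$rm, v3 = n3$rv))
  if (keepCache)
    out$cache <- list(x = x, p1 = p1, p2 = p2, p3 = p3, n1 = n1, n2 = n2,
                      n3 = n3, flat = flat, f0 = f0, concat = concat, p = p)
  out
}

# Backward pass; labels in {0,1}. Returns gradients of the mean
# cross-entropy over the batch w.r.t. every trainable weight.
backwardBatch <- function(weights, config, cache, labels) {
  ch <- config$channels
  B <- length(labels)
  Y <- rbind(1 - labels, labels)
  dz <- (cache$p - Y) / B
  dHeadW <- dz %*% t(cache$concat)
  dHeadB <- rowSums(dz)
  dConcat <- t(weights$headW) %*% dz
  df <- dConcat[seq_len(config$featureDim), , drop = FALSE] * (cache$f0 > 0)
  dFcW <- df %*% t(cache$flat)
  dFcB <- rowSums(df)
  dFlat <- t(weights$fcW) %*% df
  s <- config$inputSize / 8L
  dim(dFlat) <- c(s, s, ch[3] * B)
  dr3 <- .maxPoolBwdC(cache$p3$idx, dFlat, 2L * s, 2L * s)
  b3 <- .bnReluBwdC(dr3, cache$n3$pre, cache$n3$xhat, cache$n3$sd,
                    weights$bnG3, ch[3])
  g3 <- .convBwdC(cache$p2$y, weights$convW3, b3$dx, ch[2])
  dr2 <- .maxPoolBwdC(cache$p2$idx, g3$dx, 4L * s, 4L * s)
  b2 <- .bnReluBwdC(dr2, cache$n2$pre, cache$n2$xhat, cache$n2$sd,
                    weights$bnG2, ch[2])
  g2 <- .convBwdC(cache$p1$y, weights$convW2, b2$dx, ch[1])
  dr1 <- .maxPoolBwdC(cache$p1$idx, g2$dx, 8L * s, 8L * s)
  b1 <- .bnReluBwdC(dr1, cache$n1$pre, cache$n1$xhat, cache$n1$sd,
                    weights$bnG1, ch[1])
  g1 <- .convBwdC(cache$x, weights$convW1, b1$dx, 3L)
  list(convW1 = g1$dW, convB1 = g1$db, bnG1 = b1$dG, bnB1 = b1$dB,
       convW2 = g2$dW, convB2 = g2$db, bnG2 = b2$dG, bnB2 = b2$dB,
       convW3 = g3$dW, convB3 = g3$db, bnG3 = b3$dG, bnB3 = b3$dB,
       fcW = dFcW, fcB = dFcB, headW = dHeadW, headB = dHeadB)
}

#' Forward pass for a single slice sample
#'
#' The greyscale slice is replicated to three identical channels, the
#' backbone produces a `featureDim` feature vector, the scaled metadata
#' (age, sex, slice number) are appended — 1027 values with the defaults —
#' and the fully connected head plus softmax yield the AD-class
#' probability.
#'
#' @param sample list with `image` (2D array in [0, 1], `inputSize` pixels
#'   square, or an (H, W, 3) array of identical channels), `age_years`,
#'   `sex_code` (0/1) and `slice_number` (0-based index within the stack).
#' @param weights classifier weights (see [initWeights()]).
#' @param config a `ClassifierConfig`.
#' @return probability that the slice indicates AD.
#' @export
forward <- function(sample, weights, config, bnStats = NULL) {
  img <- sample$image
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  if (!all(dim(img) == c(config$inputSize, config$inputSize, 3L)))
    stop("image shape does not match the backbone input size")
  meta <- metaScale(sample$age_years, sample$sex_code, sample$slice_number,
                    config$nSlices)
  forwardBatch(weights, config, img, meta, bnStats)$probAD
}

#' Batch binary cross-entropy loss
#'
#' Mean over the batch of -(y log p + (1 - y) log(1 - p)), with p the
#' predicted AD-class probability clamped to [1e-7, 1 - 1e-7].
#'
#' @param probabilities predicted AD probabilities.
#' @param labels true labels in {0, 1}.
#' @return scalar loss (>= 0; 0 only when every prediction equals its
#'   label before clamping).
#' @export
batchLoss <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must have equal length")
  if (length(labels) < 1) stop("empty batch")
  p <- pmin(1 - 1e-7, pmax(1e-7, probabilities))
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Learning-rate schedule step
#'
#' Multiplies the learning rate by the decay factor when the validation
#' loss has not improved (relatively, by more than `plateauTol`) for
#' `plateauPatience` epochs since the last decay; at most `maxLrDecays`
#' decays are ever applied.
#'
#' @param state list with `valLoss` (per-epoch validation-loss history),
#'   `lr` (current rate), `decays` (decays applied so far) and
#'   `lastDecayEpoch`.
#' @param config a `TrainConfig`.
#' @return the updated state.
#' @export
lrScheduleStep <- function(state, config) {
  vl <- state$valLoss
  n <- length(vl)
  if (n < 1) stop("lrScheduleStep needs at least one validation-loss entry")
  pat <- config$plateauPatience
  start <- max(1L, state$lastDecayEpoch + 1L)
  if (n - start + 1L <= pat) return(state)
  recent <- vl[(n - pat + 1L):n]
  before <- vl[start:(n - pat)]
  improved <- min(recent) < (1 - config$plateauTol) * min(before)
  if (!improved && state$decays < config$maxLrDecays) {
    state$lr <- state$lr * config$lrDecayFactor
    state$decays <- state$decays + 1L
    state$lastDecayEpoch <- n
  }
  state
}

#' Early-stopping check
#'
#' Training stops when the moving average (window `earlyStopWindow`) of
#' subject-level validation accuracy has improved by no more than
#' `earlyStopDelta` over the last `earlyStopWindow` epochs.
#'
#' @param valAccuracy per-epoch validation-accuracy history.
#' @param config a `TrainConfig`.
#' @return TRUE if training should stop.
#' @export
earlyStopCheck <- function(valAccuracy, config) {
  w <- config$earlyStopWindow
  n <- length(valAccuracy)
  if (n < w + 1L)
    stop("earlyStopCheck needs at least earlyStopWindow + 1 entries")
  ma <- function(t) mean(valAccuracy[max(1L, t - w + 1L):t])
  improvement <- ma(n) - ma(n - w)
  # 1e-12 slack so an improvement of exactly delta stops despite
  # floating-point accumulation in the moving averages
  improvement <= config$earlyStopDelta + 1e-12
}

nesterovStep <- function(weights, velocity, grads, lr, mu, wd) {
  for (nm in names(weights)) {
    g <- grads[[nm]] + wd * weights[[nm]]
    velocity[[nm]] <- mu * velocity[[nm]] + g
    weights[[nm]] <- weights[[nm]] - lr * (g + mu * velocity[[nm]])
  }
  list(weights = weights, velocity = velocity)
}

# Assemble the (H, W, 3*B) batch array for a set of slice indices of a
# slice dataset; training batches are augmented at native resolution, then
# resized to the backbone input size.
assembleBatch <- function(ds, idx, config, augment = NULL) {
  s <- config$inputSize
  B <- length(idx)
  if (!is.null(augment)) {
    par <- rbind(runif(B, augment$rotationDeg[1], augment$rotationDeg[2]),
                 runif(B, augment$scale[1], augment$scale[2]),
                 runif(B, augment$translationPx[1], augment$translationPx[2]),
                 runif(B, augment$translationPx[1], augment$translationPx[2]),
                 runif(B, augment$contrast[1], augment$contrast[2]),
                 runif(B, augment$gamma[1], augment$gamma[2]))
    crop <- if (is.null(config$cropSize)) -1L else config$cropSize
    return(.augmentBatchC(ds$native[, , idx, drop = FALSE], par, crop, s))
  }
  x <- array(0, dim = c(s, s, 3L * B))
  for (b in seq_len(B))
    x[, , 3L * (b - 1L) + 1:3] <- ds$images[, , idx[b]]
  x
}

# Subject-level probabilities: average the slice probabilities per subject.
subjectProbs <- function(sliceProbs, sliceSubject) {
  tapply(sliceProbs, sliceSubject, mean)
}

#' Train one cross-validation fold
#'
#' Runs epochs of shuffled, augmented mini-batches with Nesterov-momentum
#' SGD and weight decay; after every epoch the subject-level validation
#' accuracy (slice probabilities averaged per subject, threshold 0.5) and
#' slice-level validation loss are recorded, the learning-rate schedule and
#' early-stopping rule applied, and the weights of the best
#' validation-accuracy epoch retained.
#'
#' @param ds slice dataset from [sliceDataset()].
#' @param trainSubjects,valSubjects disjoint subject-id vectors.
#' @param cconfig a `ClassifierConfig`.
#' @param tconfig a `TrainConfig`.
#' @param aconfig an `AugmentConfig` applied to training slices only, or
#'   NULL to disable augmentation.
#' @param seed RNG seed (weights, shuffling, augmentation draws).
#' @return A [SliceClassifier-class].
#' @export
trainFold <- function(ds, trainSubjects, valSubjects, cconfig, tconfig,
                      aconfig = augmentConfig(), seed = tconfig$seed) {
  if (length(trainSubjects) == 0 || length(valSubjects) == 0)
    stop("empty training or validation set")
  if (length(intersect(trainSubjects, valSubjects)) > 0)
    stop("training and validation subjects must be disjoint")
  trainIdx <- which(ds$sliceSubject %in% trainSubjects)
  valIdx <- which(ds$sliceSubject %in% valSubjects)
  valLabels <- ds$subjectLabel[match(
    sort(unique(ds$sliceSubject[valIdx])),
    names(ds$subjectLabel))]
  set.seed(seed)
  weights <- initWeights(cconfig, seed = sample.int(1e6, 1))
  velocity <- lapply(weights, function(w) w * 0)
  bnStats <- initBnStats(cconfig)
  lrState <- list(valLoss = numeric(0), lr = tconfig$baseLr, decays = 0L,
                  lastDecayEpoch = 0L)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     trainLoss = numeric(0), valLoss = numeric(0),
                     valAccuracy = numeric(0), decays = integer(0))
  valAccHist <- numeric(0)
  best <- list(acc = -1, weights = weights, bnStats = bnStats)
  for (epoch in seq_len(tconfig$maxEpochs)) {
    perm <- sample(trainIdx)
    epochLoss <- 0
    nb <- 0L
    for (b0 in seq(1L, length(perm), by = tconfig$batchSize)) {
      bi <- perm[b0:min(length(perm), b0 + tconfig$batchSize - 1L)]
      x <- assembleBatch(ds, bi, cconfig, augment = aconfig)
      fw <- forwardBatch(weights, cconfig, x, ds$meta[, bi, drop = FALSE],
                         bnStats, training = TRUE, keepCache = TRUE)
      bnStats <- fw$bnStats
      epochLoss <- epochLoss + batchLoss(fw$probAD, ds$labels[bi])
      nb <- nb + 1L
      grads <- backwardBatch(weights, cconfig, fw$cache, ds$labels[bi])
      upd <- nesterovStep(weights, velocity, grads, lrState$lr,
                          tconfig$momentum, tconfig$weightDecay)
      weights <- upd$weights
      velocity <- upd$velocity
    }
    vp <- predictSliceProbs(weights, cconfig, ds, valIdx, bnStats)
    valLoss <- batchLoss(vp, ds$labels[valIdx])
    sp <- subjectProbs(vp, ds$sliceSubject[valIdx])
    valAcc <- mean((sp >= 0.5) == (valLabels[names(sp)] == 1))
    valAccHist <- c(valAccHist, valAcc)
    lrState$valLoss <- c(lrState$valLoss, valLoss)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lrState$lr,
                                   trainLoss = epochLoss / nb,
                                   valLoss = valLoss, valAccuracy = valAcc,
                                   decays = lrState$decays))
    if (valAcc > best$acc)
      best <- list(acc = valAcc, weights = weights, bnStats = bnStats)
    lrState <- lrScheduleStep(lrState, tconfig)
    # start checking once two full windows exist, so the cold-start
    # plateau of from-scratch training does not trigger a premature stop
    if (length(valAccHist) >= 2L * tconfig$earlyStopWindow &&
        earlyStopCheck(valAccHist, tconfig))
      break
  }
  new("SliceClassifier", weights = best$weights, config = cconfig,
      bnStats = best$bnStats, history = hist,
      valSubjects = as.character(valSubjects))
}

# Predict slice-level AD probabilities for dataset rows `idx` (no
# augmentation; pre-resized images, running batch-norm statistics).
predictSliceProbs <- function(weights, config, ds, idx, bnStats = NULL) {
  out <- numeric(length(idx))
  step <- 256L
  for (b0 in seq(1L, length(idx), by = step)) {
    bi <- idx[b0:min(length(idx), b0 + step - 1L)]
    x <- assembleBatch(ds, bi, config, augment = NULL)
    out[b0:(b0 + length(bi) - 1L)] <-
      forwardBatch(weights, config, x, ds$meta[, bi, drop = FALSE],
                   bnStats)$probAD
  }
  out
}
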