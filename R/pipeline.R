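#' Assemble a slice dataset for training and evaluation
#'
#' Flattens per-subject [SliceStack-class] objects into slice-level arrays:
#' native-resolution slices (kept for augmentation), slices pre-resized to
#' the backbone input size, scaled metadata (age / 100, sex, slice number /
#' nSlices), labels (AD = 1, CN = 0) and the subject id of every slice.
#'
#' @param stacks named list of [SliceStack-class] objects (names = subject
#'   ids).
#' @param subjects data.frame with subject_id, age_years, sex, diagnosis.
#' @param cconfig a `ClassifierConfig`.
#' @return a list of class `SliceDataset`.
#' @export
sliceDataset <- function(stacks, subjects, cconfig) {
  stopifnot(all(names(stacks) %in% subjects$subject_id))
  ns <- vapply(stacks, nSlices, integer(1))
  if (length(unique(ns)) != 1)
    stop("all stacks must have the same slice count")
  k <- ns[[1]]
  ids <- names(stacks)
  total <- k * length(ids)
  d <- dim(stacks[[1]]@slices)
  s <- cconfig$inputSize
  # native slices are kept for augmentation; when a centre crop is
  # configured, retain only the crop plus a margin for the warp to draw on
  nd <- d[1:2]
  if (!is.null(cconfig$cropSize))
    nd <- pmin(nd, cconfig$cropSize + 16L)
  cropStore <- function(img) {
    o1 <- (dim(img)[1] - nd[1]) %/% 2
    o2 <- (dim(img)[2] - nd[2]) %/% 2
    img[o1 + seq_len(nd[1]), o2 + seq_len(nd[2]), drop = FALSE]
  }
  native <- array(0, dim = c(nd[1], nd[2], total))
  images <- array(0, dim = c(s, s, total))
  meta <- matrix(0, nrow = 3, ncol = total)
  labels <- numeric(total)
  sliceSubject <- character(total)
  row <- subjects[match(ids, subjects$subject_id), ]
  for (i in seq_along(ids)) {
    sl <- stacks[[i]]@slices
    pos <- (i - 1L) * k + seq_len(k)
    for (j in seq_len(k)) {
      native[, , pos[j]] <- cropStore(sl[, , j])
      images[, , pos[j]] <- prepSliceImage(sl[, , j], cconfig)
    }
    meta[, pos] <- metaScale(row$age_years[i], row$sex[i], seq_len(k) - 1L,
                             cconfig$nSlices)
    labels[pos] <- as.numeric(row$diagnosis[i] == "AD")
    sliceSubject[pos] <- ids[i]
  }
  subjectLabel <- setNames(as.numeric(row$diagnosis == "AD"), ids)
  structure(list(native = native, images = images, meta = meta,
                 labels = labels, sliceSubject = sliceSubject,
                 subjectLabel = subjectLabel, subjects = row,
                 nSlices = k, cconfig = cconfig),
            class = "SliceDataset")
}

#' Split subjects into development and test sets
#'
#' Class-wise random split: per class, floor(devFraction * n) subjects go
#' to development, the rest to test (so 195 + 195 at 80% gives 156 + 156
#' development and 39 + 39 test).
#'
#' @param subjects data.frame with subject_id and diagnosis.
#' @param devFraction development fraction (default 0.8).
#' @param seed RNG seed.
#' @return list with `development`, `test` (subject-id vectors) and
#'   `trialSeed`.
#' @export
splitDevTest <- function(subjects, devFraction = 0.8, seed = 1L) {
  classes <- unique(subjects$diagnosis)
  if (length(classes) != 2) stop("exactly two diagnosis classes required")
  if (devFraction <= 0 || devFraction >= 1)
    stop("devFraction must lie strictly between 0 and 1")
  set.seed(seed)
  dev <- character(0)
  tst <- character(0)
  for (cl in sort(classes)) {
    ids <- subjects$subject_id[subjects$diagnosis == cl]
    if (length(ids) < 2) stop("class ", cl, " has fewer than 2 subjects")
    nd <- floor(devFraction * length(ids))
    if (nd < 1 || nd >= length(ids))
      stop("devFraction leaves an empty development or test set for ", cl)
    pick <- sample(ids, nd)
    dev <- c(dev, pick)
    tst <- c(tst, setdiff(ids, pick))
  }
  list(development = dev, test = tst, trialSeed = as.integer(seed))
}

#' Stratified k-fold partition of the development set
#'
#' Shuffles each class and deals subjects round-robin into k folds, so
#' every fold's validation set has per-class counts within 1 of equal
#' shares and the folds partition the development set.
#'
#' @param devIds development subject ids.
#' @param labels named vector (or vector aligned with devIds) of class
#'   labels.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return list of k character vectors (validation subjects per fold).
#' @export
stratifiedKFold <- function(devIds, labels, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (!is.null(names(labels))) labels <- labels[devIds]
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in sort(unique(as.character(labels)))) {
    ids <- sample(devIds[labels == cl])
    if (length(ids) < k) stop("class ", cl, " has fewer subjects than folds")
    assign <- rep_len(seq_len(k), length(ids))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], ids[assign == f])
  }
  folds
}

#' Subject-level ensemble prediction
#'
#' For each fold model the per-slice AD probabilities of the stack are
#' averaged; the final prediction is the mean of the fold-level averages.
#' Invariant under permutations of slice order and fold order.
#'
#' @param ensemble a [ClassifierEnsemble-class].
#' @param stack a [SliceStack-class].
#' @param metadata list with `age_years` and `sex` (0/1).
#' @return probability of AD for the subject.
#' @export
predictSubject <- function(ensemble, stack, metadata) {
  cconfig <- ensemble@models[[1]]@config
  k <- nSlices(stack)
  s <- cconfig$inputSize
  x <- array(0, dim = c(s, s, 3L * k))
  for (j in seq_len(k)) {
    img <- prepSliceImage(stack@slices[, , j], cconfig)
    x[, , 3L * (j - 1L) + 1:3] <- img
  }
  meta <- metaScale(metadata$age_years, metadata$sex, seq_len(k) - 1L,
                    cconfig$nSlices)
  foldMeans <- vapply(ensemble@models, function(m) {
    mean(forwardBatch(m@weights, cconfig, x, meta, m@bnStats)$probAD)
  }, numeric(1))
  mean(foldMeans)
}

# Ensemble predictions for a set of subjects of a SliceDataset.
predictDataset <- function(ensemble, ds, subjectIds) {
  idx <- which(ds$sliceSubject %in% subjectIds)
  probs <- vapply(ensemble@models, function(m) {
    predictSliceProbs(m@weights, ds$cconfig, ds, idx, m@bnStats)
  }, numeric(length(idx)))
  sliceMean <- rowMeans(matrix(probs, nrow = length(idx)))
  sp <- subjectProbs(sliceMean, ds$sliceSubject[idx])
  data.frame(subject_id = names(sp), probability = as.numeric(sp),
             label = as.numeric(ds$subjectLabel[names(sp)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# ROC-derived metric block for a prediction data.frame.
metricBlock <- function(pred) {
  roc <- rocAuc(pred$probability, pred$label)
  op <- youdenPoint(roc)
  ci <- aucConfidenceInterval(roc)
  list(auc = roc@auc, aucCiLow = ci[1], aucCiHigh = ci[2],
       accuracy = op@accuracy, sensitivity = op@sensitivity,
       specificity = op@specificity, threshold = op@threshold,
       aucVariance = roc@aucVariance)
}

#' Run one trial of the evaluation protocol
#'
#' Splits dataset A into development (80%) and test (20%) sets class-wise,
#' trains a stratified k-fold ensemble on the development set, and
#' evaluates the ensemble on (i) dataset A's held-out test set
#' (within-dataset) and (ii) the entirety of dataset B (between-dataset),
#' when one is given.
#'
#' @param datasetA a `SliceDataset` (the development population).
#' @param datasetB optional second `SliceDataset` evaluated in full.
#' @param cconfig,tconfig,aconfig classifier / training / augmentation
#'   configurations.
#' @param trialSeed seed for this trial (split, folds, training).
#' @param devFraction development fraction.
#' @param k number of folds.
#' @return list with the `split`, the `ensemble`, `within` and `between`
#'   metric blocks and per-subject `predictions`.
#' @export
runTrial <- function(datasetA, datasetB = NULL, cconfig, tconfig,
                     aconfig = augmentConfig(), trialSeed = 1L,
                     devFraction = 0.8, k = 5L) {
  split <- splitDevTest(datasetA$subjects, devFraction, seed = trialSeed)
  folds <- stratifiedKFold(split$development, datasetA$subjectLabel, k = k,
                           seed = derivedSeed(trialSeed, 17))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    models[[f]] <- trainFold(datasetA,
                             setdiff(split$development, folds[[f]]),
                             folds[[f]], cconfig, tconfig, aconfig,
                             seed = derivedSeed(trialSeed, 100 + f))
  }
  ensemble <- new("ClassifierEnsemble", models = models)
  withinPred <- predictDataset(ensemble, datasetA, split$test)
  within <- metricBlock(withinPred)
  between <- NULL
  betweenPred <- NULL
  if (!is.null(datasetB)) {
    betweenPred <- predictDataset(ensemble, datasetB,
                                  names(datasetB$subjectLabel))
    between <- metricBlock(betweenPred)
  }
  list(split = split, ensemble = ensemble, within = within,
       between = between,
       predictions = list(within = withinPred, between = betweenPred))
}

#' Run the repeated-trials experiment
#'
#' Repeats [runTrial()] `nTrials` times with deterministic per-trial seeds
#' (master seed + trial index), collects per-trial within- and
#' between-dataset metrics, aggregates them as mean and sample SD, and —
#' when a second dataset is present — compares within- vs between-dataset
#' performance per metric with a paired t-test.
#'
#' @inheritParams runTrial
#' @param nTrials number of repeated trials (>= 2).
#' @param seed master seed.
#' @param keepEnsembles retain the trained ensembles in the result
#'   (memory-heavy; default FALSE).
#' @return list of class `EvaluationReport`: `trials` (per-trial metric
#'   rows), `summary` (mean/SD per metric), `comparisons` (paired tests)
#'   and `predictions`.
#' @export
runExperiment <- function(datasetA, datasetB = NULL, cconfig, tconfig,
                          aconfig = augmentConfig(), nTrials = 5L,
                          seed = 1L, devFraction = 0.8, k = 5L,
                          keepEnsembles = FALSE) {
  if (nTrials < 2) stop("nTrials must be >= 2")
  metrics <- c("auc", "accuracy", "sensitivity", "specificity")
  rows <- list()
  predictions <- list()
  ensembles <- list()
  for (tr in seq_len(nTrials)) {
    res <- runTrial(datasetA, datasetB, cconfig, tconfig, aconfig,
                    trialSeed = as.integer(seed + tr), devFraction, k)
    rows[[tr]] <- data.frame(
      trial = tr, arm = c("within", if (!is.null(res$between)) "between"),
      do.call(rbind, lapply(Filter(Negate(is.null),
                                   list(res$within, res$between)),
                            function(m) as.data.frame(m[c(metrics,
                                                          "aucCiLow",
                                                          "aucCiHigh")]))))
    predictions[[tr]] <- res$predictions
    if (keepEnsembles) ensembles[[tr]] <- res$ensemble
  }
  trials <- do.call(rbind, rows)
  summarise <- function(arm) {
    sub <- trials[trials$arm == arm, ]
    if (nrow(sub) == 0) return(NULL)
    do.call(rbind, lapply(metrics, function(m) {
      ts <- trialSummary(sub[[m]])
      data.frame(arm = arm, metric = m, mean = ts["mean"], sd = ts["sd"],
                 row.names = NULL)
    }))
  }
  summary <- rbind(summarise("within"), summarise("between"))
  comparisons <- NULL
  if (!is.null(datasetB)) {
    comparisons <- lapply(setNames(metrics, metrics), function(m) {
      w <- trials[[m]][trials$arm == "within"]
      b <- trials[[m]][trials$arm == "between"]
      tt <- tryCatch(pairedTtest(w, b), error = function(e) NULL)
      if (is.null(tt)) return(NULL)
      list(statistic = tt@statistic, df = tt@df, pValue = tt@pValue)
    })
  }
  structure(list(trials = trials, summary = summary,
                 comparisons = comparisons, predictions = predictions,
                 ensembles = if (keepEnsembles) ensembles else NULL,
                 nTrials = nTrials, seed = seed),
            class = "EvaluationReport")
}

#' Generate and preprocess a phantom dataset
#'
#' Streams phantom subjects through the full preprocessing chain — volume
#' generation, two-step rigid alignment to a phantom-space template, and
#' medial-temporal coronal slice extraction — and assembles the resulting
#' stacks into a `SliceDataset`, never holding more than one 3D volume in
#' memory.
#'
#' @param spec a `PhantomSpec`.
#' @param nAD,nCN subjects per class.
#' @param cconfig a `ClassifierConfig`.
#' @param seed RNG seed for this dataset.
#' @param template optional pre-built [BrainTemplate-class]; built from CN
#'   phantoms when NULL.
#' @param nSlices slices per subject; default keeps the 30 mm
#'   medial-temporal span (30 slices at 1 mm, 15 at 2 mm).
#' @param settings registration settings.
#' @return list with `dataset` (a `SliceDataset`) and `template`.
#' @export
preparePhantomDataset <- function(spec, nAD, nCN, cconfig, seed = spec$seed,
                                  template = NULL,
                                  nSlices = round(30 / spec$voxelSpacingMm),
                                  settings = registrationSettings()) {
  if (is.null(template))
    template <- phantomTemplate(spec, seed = derivedSeed(seed, 555),
                                settings = settings)
  meta <- cohortMetadata(spec, nAD, nCN, seed)
  stacks <- vector("list", nrow(meta))
  names(stacks) <- meta$subject_id
  for (i in seq_len(nrow(meta))) {
    g <- generateVolume(spec, as.list(meta[i, , drop = FALSE]),
                        seed = derivedSeed(seed, i))
    aligned <- twoStepAlign(g$volume, template, settings)
    stacks[[i]] <- extractCoronalSlices(aligned$volume, template,
                                        nSlices = nSlices,
                                        subjectRef = meta$subject_id[i])
  }
  cconfig$nSlices <- as.integer(nSlices)
  list(dataset = sliceDataset(stacks, meta, cconfig), template = template)
}
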