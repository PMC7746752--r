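#' Write a slice stack to disk
#'
#' The slices are stored as a 3D NIfTI (H x W x n) next to a JSON sidecar
#' holding the coronal indices and the subject reference, so the stack
#' round-trips exactly through [readSliceStack()].
#'
#' @param stack a [SliceStack-class].
#' @param path output NIfTI path (.nii or .nii.gz); the sidecar gets the
#'   extension .json.
#' @return the path, invisibly.
#' @export
writeSliceStack <- function(stack, path) {
  RNifti::writeNifti(RNifti::asNifti(stack@slices), path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(subjectRef = stack@subjectRef,
                            sliceIndices = stack@sliceIndices),
                       side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a slice stack written by [writeSliceStack()]
#'
#' @param path NIfTI path.
#' @return A [SliceStack-class].
#' @export
readSliceStack <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  new("SliceStack", slices = array(as.numeric(img), dim = dim(img)),
      sliceIndices = as.integer(side$sliceIndices),
      subjectRef = side$subjectRef)
}

#' Write a template to disk
#'
#' Volume and mask as NIfTI plus a JSON sidecar with the anchor index and
#' mask path.
#'
#' @param template a [BrainTemplate-class].
#' @param prefix output path prefix; writes prefix.nii.gz,
#'   prefix_mask.nii.gz and prefix.json.
#' @return the prefix, invisibly.
#' @export
writeTemplate <- function(template, prefix) {
  writeVolume(template@volume, paste0(prefix, ".nii.gz"))
  maskVol <- brainVolume(template@brainMask + 0, template@volume@spacing)
  writeVolume(maskVol, paste0(prefix, "_mask.nii.gz"))
  jsonlite::write_json(list(anchorIndex = template@anchorIndex,
                            maskPath = paste0(basename(prefix),
                                              "_mask.nii.gz")),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read a template written by [writeTemplate()]
#'
#' @param prefix path prefix used at write time.
#' @return A [BrainTemplate-class].
#' @export
readTemplate <- function(prefix) {
  vol <- readVolume(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mask <- readVolume(file.path(dirname(prefix), side$maskPath))
  new("BrainTemplate", volume = vol,
      brainMask = array(as.integer(mask@data > 0.5), dim = dim(mask@data)),
      anchorIndex = as.integer(side$anchorIndex))
}

#' Read / write subject metadata tables
#'
#' CSV with header subject_id, age_years, sex, diagnosis.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readSubjects <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "sex", "diagnosis")
  if (!all(need %in% names(df)))
    stop("subjects CSV must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname readSubjects
#' @param subjects data.frame with the four required columns.
#' @export
writeSubjects <- function(subjects, path) {
  write.csv(subjects[, c("subject_id", "age_years", "sex", "diagnosis")],
            path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' The desk-scale study conditions: 96-voxel 2 mm phantoms with a 0.3
#' atrophy effect, 15 medial-temporal slices (the 30 mm span), the
#' tiny_cnn backbone at 64 features and 32 px input, and the training
#' recipe (batch 64, Nesterov SGD, lr 0.001, weight decay 5e-5).
#'
#' @return nested configuration list.
#' @export
defaultRunConfig <- function() {
  list(phantom = list(gridSize = 96L, voxelSpacingMm = 2, atrophyEffect = 0.3,
                      intensityNoiseSd = 0.08, misalignRotDegMax = 8,
                      misalignTransMmMax = 8, mtlJitterSd = 0.05),
       preprocess = list(nSlices = NULL,
                         sliceDirection = "posterior-to-anterior",
                         shrinkFactors = c(4L, 2L), maxit = c(50L, 40L)),
       augment = list(rotationDeg = c(-5, 5), scale = c(0.95, 1.05),
                      translationPx = c(-2, 2), contrast = c(0.9, 1.1),
                      gamma = c(0.9, 1.1)),
       model = list(backbone = "tiny_cnn", featureDim = 64L,
                    inputSize = 32L, cropSize = 48L),
       train = list(batchSize = 64L, baseLr = 0.001, weightDecay = 5e-5,
                    momentum = 0.9, lrDecayFactor = 0.1, maxLrDecays = 3L,
                    plateauTol = 1e-4, plateauPatience = 5L,
                    earlyStopDelta = 5e-4, earlyStopWindow = 5L,
                    maxEpochs = 15L),
       pipeline = list(nAD = 60L, nCN = 60L, nADB = 40L, nCNB = 40L,
                       useDatasetB = FALSE, devFraction = 0.8, k = 5L,
                       nTrials = 3L, seed = 1L),
       output = NULL)
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read and validate a YAML run configuration
#'
#' Unspecified fields fall back to [defaultRunConfig()]; every block is
#' validated through its module's constructor before any computation.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- mergeConfig(cfg, yaml::read_yaml(path))
  }
  # validate by construction
  do.call(phantomSpec, cfg$phantom)
  do.call(augmentConfig, cfg$augment)
  do.call(classifierConfig, cfg$model)
  do.call(trainConfig, cfg$train)
  with(cfg$pipeline, {
    if (devFraction <= 0 || devFraction >= 1) stop("invalid devFraction")
    if (k < 2) stop("k must be >= 2")
  })
  cfg
}

#' Run the configured phantom experiment
#'
#' Builds the phantom dataset(s) with the configured study conditions,
#' runs the repeated-trials protocol, and optionally writes report.json,
#' per-subject prediction CSVs and the resolved configuration to the
#' output directory.
#'
#' @param config configuration list from [readRunConfig()].
#' @param seed optional master-seed override.
#' @param outputDir optional output directory.
#' @return An `EvaluationReport` (see [runExperiment()]).
#' @export
experimentFromConfig <- function(config = readRunConfig(), seed = NULL,
                                 outputDir = config$output) {
  pl <- config$pipeline
  if (!is.null(seed)) pl$seed <- as.integer(seed)
  spec <- do.call(phantomSpec, c(config$phantom, list(seed = pl$seed)))
  cconfig <- do.call(classifierConfig, config$model)
  tconfig <- do.call(trainConfig, config$train)
  aconfig <- do.call(augmentConfig, config$augment)
  settings <- registrationSettings(config$preprocess$shrinkFactors,
                                   config$preprocess$maxit)
  nsl <- config$preprocess$nSlices
  if (is.null(nsl)) nsl <- round(30 / spec$voxelSpacingMm)
  prepA <- preparePhantomDataset(spec, pl$nAD, pl$nCN, cconfig,
                                 seed = derivedSeed(pl$seed, 1000001),
                                 nSlices = nsl, settings = settings)
  datasetB <- NULL
  if (isTRUE(pl$useDatasetB)) {
    prepB <- preparePhantomDataset(spec, pl$nADB, pl$nCNB, cconfig,
                                   seed = derivedSeed(pl$seed, 2000002),
                                   template = prepA$template,
                                   nSlices = nsl, settings = settings)
    datasetB <- prepB$dataset
  }
  cconfig$nSlices <- as.integer(nsl)
  report <- runExperiment(prepA$dataset, datasetB, cconfig, tconfig,
                          aconfig, nTrials = pl$nTrials, seed = pl$seed,
                          devFraction = pl$devFraction, k = pl$k)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeReport(report, file.path(outputDir, "report.json"))
    jsonlite::write_json(config, file.path(outputDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (tr in seq_along(report$predictions)) {
      pr <- report$predictions[[tr]]$within
      write.csv(pr, file.path(outputDir,
                              sprintf("predictions_trial%d_within.csv", tr)),
                row.names = FALSE)
      if (!is.null(report$predictions[[tr]]$between))
        write.csv(report$predictions[[tr]]$between,
                  file.path(outputDir,
                            sprintf("predictions_trial%d_between.csv", tr)),
                  row.names = FALSE)
    }
  }
  report
}

#' Write an evaluation report as JSON
#'
#' Deterministic output: no timestamps, full-precision numbers.
#'
#' @param report an `EvaluationReport`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path) {
  out <- list(seed = report$seed, nTrials = report$nTrials,
              trials = report$trials, summary = report$summary,
              comparisons = report$comparisons,
              predictions = report$predictions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Append a structured JSON log line
#'
#' @param path log file (JSON-lines).
#' @param stage pipeline stage name.
#' @param ... named fields to record.
#' @return invisibly, the line written.
#' @export
logJsonLine <- function(path, stage, ...) {
  line <- jsonlite::toJSON(c(list(stage = stage), list(...)),
                           auto_unbox = TRUE, digits = NA)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(line)
}
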