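#' Phantom generation parameters
#'
#' Defines the synthetic study conditions: a head-like object built from
#' nested ellipsoids — a bright outer shell (scalp/skull surrogate,
#' intensity 1.0), an interior brain ellipsoid (intensity 0.6) and two
#' bilateral medial-temporal ellipsoids (intensity 0.8) whose volume is
#' reduced by `atrophyEffect` in the AD class — corrupted by a random rigid
#' misalignment and additive Gaussian noise. Anatomy is fixed in millimetre
#' units (head-sized), so the grid/spacing only control sampling.
#'
#' @param gridSize voxels per axis (cubic grid, >= 32).
#' @param voxelSpacingMm isotropic voxel size in mm.
#' @param atrophyEffect fractional reduction of the medial-temporal
#'   structure volume in AD relative to CN, in [0, 1).
#' @param intensityNoiseSd additive Gaussian noise SD as a fraction of the
#'   brain-tissue intensity (0.6).
#' @param misalignRotDegMax max magnitude of the random rotation per axis
#'   (degrees).
#' @param misalignTransMmMax max magnitude of the random translation per
#'   axis (mm).
#' @param mtlJitterSd SD (log scale) of the per-subject lognormal jitter on
#'   the medial-temporal volume.
#' @param ageMean,ageSd mean/SD of the simulated subject age (years),
#'   truncated to [55, 95]; identical in both classes (matched design).
#' @param femaleFraction probability of female sex, identical in both
#'   classes.
#' @param seed default RNG seed used when none is supplied to generators.
#' @return A validated list of class `PhantomSpec`.
#' @export
phantomSpec <- function(gridSize = 96L, voxelSpacingMm = 2,
                        atrophyEffect = 0.3, intensityNoiseSd = 0.08,
                        misalignRotDegMax = 8, misalignTransMmMax = 8,
                        mtlJitterSd = 0.05, ageMean = 74.6, ageSd = 7,
                        femaleFraction = 0.467, seed = 1L) {
  spec <- list(gridSize = as.integer(gridSize),
               voxelSpacingMm = as.numeric(voxelSpacingMm),
               atrophyEffect = as.numeric(atrophyEffect),
               intensityNoiseSd = as.numeric(intensityNoiseSd),
               misalignRotDegMax = as.numeric(misalignRotDegMax),
               misalignTransMmMax = as.numeric(misalignTransMmMax),
               mtlJitterSd = as.numeric(mtlJitterSd),
               ageMean = ageMean, ageSd = ageSd,
               femaleFraction = femaleFraction, seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  validatePhantomSpec(spec)
  spec
}

validatePhantomSpec <- function(spec) {
  if (spec$gridSize < 32L) stop("gridSize must be >= 32")
  if (spec$voxelSpacingMm <= 0) stop("voxelSpacingMm must be positive")
  if (spec$atrophyEffect < 0 || spec$atrophyEffect >= 1)
    stop("atrophyEffect must be in [0, 1)")
  if (spec$intensityNoiseSd < 0 || spec$misalignRotDegMax < 0 ||
      spec$misalignTransMmMax < 0 || spec$mtlJitterSd < 0)
    stop("noise, jitter and misalignment magnitudes must be >= 0")
  geo <- phantomGeometry()
  halfFov <- spec$gridSize * spec$voxelSpacingMm / 2
  if (halfFov < max(geo$shellOuter) + spec$misalignTransMmMax + 2)
    stop("phantom geometry infeasible: structure does not fit in the grid ",
         "(half field of view ", halfFov, " mm < required ",
         max(geo$shellOuter) + spec$misalignTransMmMax + 2, " mm)")
  invisible(TRUE)
}

# Fixed anatomy in mm (semi-axes; world origin at the head centre).
# Intensities follow the T1-like convention: background 0, shell 1.0,
# brain 0.6, ventricle 0.3, medial-temporal structure 0.8 before noise.
# Distinct semi-axes per axis and the dark ventricle break rotational
# symmetry so that all three rotations are identifiable by registration.
phantomGeometry <- function() {
  list(brain = c(54, 67, 47), brainIntensity = 0.6,
       shellInner = c(62, 75, 55), shellOuter = c(68, 81, 61),
       shellIntensity = 1.0,
       ventricleCenter = c(0, 8, 8), ventricleSemi = c(16, 30, 10),
       ventricleIntensity = 0.3,
       mtlCenterL = c(-28, -10, -15), mtlCenterR = c(28, -10, -15),
       mtlSemi = c(10, 15, 8), mtlIntensity = 0.8)
}

#' Analytic anchor coronal index of the phantom
#'
#' The 0-based index of the first coronal plane at or anterior to the
#' posterior-most extent of the medial-temporal structures in the canonical
#' (unmisaligned) phantom frame — the analogue of anchoring on the
#' hippocampal body in a real template.
#'
#' @param spec a `PhantomSpec`.
#' @return integer slice index.
#' @export
analyticAnchorIndex <- function(spec) {
  geo <- phantomGeometry()
  yPosterior <- geo$mtlCenterL[2] - geo$mtlSemi[2]
  n <- spec$gridSize
  as.integer(ceiling(yPosterior / spec$voxelSpacingMm + (n - 1) / 2))
}

# Deterministic per-subject seed stream derived from a master seed.
derivedSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647)
}

# Evaluate the phantom model at world points mapped through the inverse
# of the misalignment transform (compiled renderer). Ellipsoid boundaries
# carry a partial-volume ramp about one voxel wide, as in real MR
# sampling; hard-edged rendering would alias on the grid and bias
# intensity-based registration toward grid-aligned poses.
evalPhantomModel <- function(dims, spacing, transform, mtlScale) {
  geo <- phantomGeometry()
  Rinv <- t(eulerMatrix(transform@rotations))
  semi <- geo$mtlSemi * mtlScale
  ell <- rbind(c(0, 0, 0, geo$brain),
               c(0, 0, 0, geo$shellOuter),
               c(0, 0, 0, geo$shellInner),
               c(geo$ventricleCenter, geo$ventricleSemi),
               c(geo$mtlCenterL, semi),
               c(geo$mtlCenterR, semi))
  .phantomRenderC(as.integer(dims), as.numeric(spacing), Rinv,
                  transform@translations, ell,
                  c(geo$brainIntensity, geo$shellIntensity,
                    geo$ventricleIntensity, geo$mtlIntensity),
                  mean(spacing))
}

#' Generate one phantom volume
#'
#' Draws a random rigid misalignment and a lognormal medial-temporal volume
#' jitter, evaluates the phantom anatomy through the misalignment, and adds
#' Gaussian noise. For AD subjects the medial-temporal volume is scaled by
#' (1 - atrophyEffect). Generation is a pure function of (spec,
#' subjectParams, seed).
#'
#' @param spec a `PhantomSpec` (see [phantomSpec()]).
#' @param subjectParams list with `subject_id`, `age_years`, `sex`
#'   (0 = male, 1 = female) and `diagnosis` ("AD" or "CN").
#' @param seed integer RNG seed for this subject.
#' @return list with `volume` (a [BrainVolume-class]) and `subject` (the
#'   parameters plus `trueTransform` and `trueMtlVolumeMm3` ground truth).
#' @export
generateVolume <- function(spec, subjectParams, seed = spec$seed) {
  validatePhantomSpec(spec)
  stopifnot(subjectParams$diagnosis %in% c("AD", "CN"))
  geo <- phantomGeometry()
  set.seed(seed)
  rot <- runif(3, -spec$misalignRotDegMax, spec$misalignRotDegMax)
  trn <- runif(3, -spec$misalignTransMmMax, spec$misalignTransMmMax)
  jitter <- exp(rnorm(1, 0, spec$mtlJitterSd))
  atrophy <- if (subjectParams$diagnosis == "AD") 1 - spec$atrophyEffect else 1
  volumeFactor <- atrophy * jitter
  mtlScale <- volumeFactor^(1 / 3)
  trueTransform <- rigidTransform(rot, trn)
  dims <- rep(spec$gridSize, 3L)
  spacing <- rep(spec$voxelSpacingMm, 3)
  vol <- evalPhantomModel(dims, spacing, trueTransform, mtlScale)
  if (spec$intensityNoiseSd > 0)
    vol <- vol + array(rnorm(length(vol), 0,
                             spec$intensityNoiseSd * geo$brainIntensity),
                       dim = dims)
  mtlVol <- 2 * 4 / 3 * pi * prod(geo$mtlSemi) * volumeFactor
  subject <- subjectParams
  subject$trueTransform <- trueTransform
  subject$trueMtlVolumeMm3 <- mtlVol
  list(volume = brainVolume(vol, spacing), subject = subject)
}

#' Canonical noise-free phantom
#'
#' The phantom evaluated with zero misalignment, zero noise and unit
#' medial-temporal scale; used as the standard-space reference when
#' building a template.
#'
#' @param spec a `PhantomSpec`.
#' @return A [BrainVolume-class].
#' @export
canonicalPhantom <- function(spec) {
  validatePhantomSpec(spec)
  dims <- rep(spec$gridSize, 3L)
  spacing <- rep(spec$voxelSpacingMm, 3)
  brainVolume(evalPhantomModel(dims, spacing, rigidTransform(), 1), spacing)
}

#' Ground-truth brain mask of the canonical phantom
#'
#' @param spec a `PhantomSpec`.
#' @return integer 0/1 array marking the brain ellipsoid.
#' @export
canonicalBrainMask <- function(spec) {
  geo <- phantomGeometry()
  n <- spec$gridSize
  s <- spec$voxelSpacingMm
  xs <- (seq_len(n) - 1 - (n - 1) / 2) * s
  g <- outer(outer((xs / geo$brain[1])^2, (xs / geo$brain[2])^2, "+"),
             (xs / geo$brain[3])^2, "+")
  array(as.integer(g <= 1), dim = rep(n, 3))
}

#' Simulated cohort metadata
#'
#' Ages and sexes are drawn from the same distributions in both classes
#' (age/sex-matched design); subject ids are unique.
#'
#' @param spec a `PhantomSpec`.
#' @param nAD,nCN subjects per class.
#' @param seed RNG seed.
#' @return data.frame with subject_id, age_years, sex, diagnosis.
#' @export
cohortMetadata <- function(spec, nAD, nCN, seed = spec$seed) {
  if (nAD < 1 || nCN < 1) stop("nAD and nCN must each be >= 1")
  n <- nAD + nCN
  set.seed(seed)
  age <- pmin(95, pmax(55, rnorm(n, spec$ageMean, spec$ageSd)))
  sex <- rbinom(n, 1, spec$femaleFraction)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             age_years = round(age, 1), sex = sex,
             diagnosis = rep(c("AD", "CN"), c(nAD, nCN)),
             stringsAsFactors = FALSE)
}

#' Generate a phantom cohort
#'
#' @inheritParams cohortMetadata
#' @return list of per-subject lists as returned by [generateVolume()].
#' @export
generateCohort <- function(spec, nAD, nCN, seed = spec$seed) {
  meta <- cohortMetadata(spec, nAD, nCN, seed)
  lapply(seq_len(nrow(meta)), function(i) {
    generateVolume(spec, as.list(meta[i, , drop = FALSE]),
                   seed = derivedSeed(seed, i))
  })
}

#' Build a registration template from CN volumes
#'
#' Rigidly registers every input volume to a reference (by default the
#' first input), averages the aligned volumes voxelwise, derives a brain
#' mask from the mean with [extractBrain()], and stores the anchor coronal
#' index of the medial-temporal slice range as template metadata.
#'
#' @param volumes list of [BrainVolume-class] objects on a common grid.
#' @param anchorIndex 0-based anchor coronal index to store (for phantoms,
#'   [analyticAnchorIndex()]).
#' @param reference optional [BrainVolume-class] defining template space;
#'   default is the first input volume.
#' @param settings registration settings, see [registrationSettings()].
#' @return A [BrainTemplate-class].
#' @export
buildTemplate <- function(volumes, anchorIndex, reference = NULL,
                          settings = registrationSettings()) {
  if (length(volumes) < 1) stop("need at least one CN volume")
  dims <- dim(volumes[[1]]@data)
  if (!all(vapply(volumes, function(v) identical(dim(v@data), dims),
                  logical(1))))
    stop("all template volumes must be on the same grid")
  if (is.null(reference)) reference <- volumes[[1]]
  acc <- array(0, dim = dim(reference@data))
  for (v in volumes) {
    if (identical(v@data, reference@data)) {
      acc <- acc + v@data
    } else {
      reg <- registerRigid(v, reference, settings)
      acc <- acc + reg$resampled@data
    }
  }
  meanVol <- brainVolume(acc / length(volumes), reference@spacing)
  ext <- extractBrain(meanVol)
  new("BrainTemplate", volume = meanVol, brainMask = ext$mask,
      anchorIndex = as.integer(anchorIndex))
}

#' Phantom-space template
#'
#' Builds a [BrainTemplate-class] from freshly generated CN phantoms,
#' aligned to the canonical (standard-space) phantom, with the analytic
#' anchor index from the generator geometry.
#'
#' @param spec a `PhantomSpec`.
#' @param n number of CN template subjects.
#' @param seed RNG seed for the template population (kept distinct from
#'   cohort seeds).
#' @param settings registration settings.
#' @return A [BrainTemplate-class].
#' @export
phantomTemplate <- function(spec, n = 6L, seed = spec$seed,
                            settings = registrationSettings()) {
  meta <- cohortMetadata(spec, 1, max(1L, n), derivedSeed(seed, 900001))
  meta <- meta[meta$diagnosis == "CN", , drop = FALSE]
  vols <- lapply(seq_len(nrow(meta)), function(i) {
    generateVolume(spec, as.list(meta[i, , drop = FALSE]),
                   seed = derivedSeed(seed, 900100 + i))$volume
  })
  buildTemplate(vols, analyticAnchorIndex(spec),
                reference = canonicalPhantom(spec), settings = settings)
}
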