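#' Registration settings
#'
#' Multi-resolution rigid registration over the 6 rigid parameters,
#' minimising the mean-squared intensity difference (the default
#' similarity for same-modality images; phantoms share one intensity
#' convention), initialised from intensity moments and refined by
#' L-BFGS-B with analytic metric gradients.
#'
#' @param momentInit initialise from matched intensity centroids and
#'   principal axes (recommended).
#' @param rotScale internal rotation rescaling (degrees per optimiser
#'   unit) for conditioning.
#'
#' @param shrinkFactors integer vector of pyramid shrink factors, coarse to
#'   fine (block-mean downsampling).
#' @param maxit optimizer iteration budget per level.
#' @param metric similarity metric; only "msd" is implemented.
#' @return settings list.
#' @export
registrationSettings <- function(shrinkFactors = c(4L, 2L),
                                 maxit = c(50L, 40L), metric = "msd",
                                 momentInit = TRUE, rotScale = 5) {
  stopifnot(length(shrinkFactors) == length(maxit), all(shrinkFactors >= 1))
  if (!identical(metric, "msd"))
    stop("only the mean-squared-difference metric is implemented")
  list(shrinkFactors = as.integer(shrinkFactors), maxit = as.integer(maxit),
       metric = metric, momentInit = isTRUE(momentInit),
       rotScale = rotScale)
}

# Intensity centroid and second-moment matrix of a volume array, in world
# coordinates (origin at the volume centre); background suppressed by a
# small intensity floor.
intensityMoments <- function(arr, spacing, floor = 0.1) {
  d <- dim(arr)
  w <- pmax(arr - floor, 0)
  xs <- (seq_len(d[1]) - 1 - (d[1] - 1) / 2) * spacing[1]
  ys <- (seq_len(d[2]) - 1 - (d[2] - 1) / 2) * spacing[2]
  zs <- (seq_len(d[3]) - 1 - (d[3] - 1) / 2) * spacing[3]
  s <- sum(w)
  if (s <= 0) return(list(mu = c(0, 0, 0), sigma = diag(3)))
  wx <- rowSums(w); wy <- apply(w, 2, sum); wz <- apply(w, 3, sum)
  mu <- c(sum(wx * xs), sum(wy * ys), sum(wz * zs)) / s
  X <- xs - mu[1]; Y <- ys - mu[2]; Z <- zs - mu[3]
  sig <- matrix(0, 3, 3)
  sig[1, 1] <- sum(wx * X^2)
  sig[2, 2] <- sum(wy * Y^2)
  sig[3, 3] <- sum(wz * Z^2)
  sig[1, 2] <- sig[2, 1] <- sum(apply(w, c(1, 2), sum) * outer(X, Y))
  sig[1, 3] <- sig[3, 1] <- sum(apply(w, c(1, 3), sum) * outer(X, Z))
  sig[2, 3] <- sig[3, 2] <- sum(apply(w, c(2, 3), sum) * outer(Y, Z))
  list(mu = mu, sigma = sig / s)
}

# Moments-based rigid initialisation: translation from the centroid shift,
# rotation from matched principal axes (signs chosen nearest identity).
momentInitTransform <- function(fixedArr, fixedSpacing, movArr, movSpacing) {
  mf <- intensityMoments(fixedArr, fixedSpacing)
  mm <- intensityMoments(movArr, movSpacing)
  Uf <- eigen(mf$sigma, symmetric = TRUE)$vectors
  Um <- eigen(mm$sigma, symmetric = TRUE)$vectors
  best <- diag(3)
  bestTr <- -Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    R <- Um %*% diag(c(s1, s2, s3)) %*% t(Uf)
    if (det(R) < 0) next
    if (sum(diag(R)) > bestTr) { bestTr <- sum(diag(R)); best <- R }
  }
  rigidTransform(eulerFromMatrix(best), as.numeric(mm$mu - best %*% mf$mu))
}

#' Rigid registration of a moving to a fixed volume
#'
#' Estimates the 6-parameter rigid transform (3 rotations, 3 translations;
#' determinant of the linear part is exactly 1, so morphology is preserved)
#' that minimises the mean-squared intensity difference. The search is
#' initialised from matched intensity centroids and principal axes, then
#' refined by L-BFGS-B with the analytic metric gradient over a
#' coarse-to-fine resolution pyramid (rotations internally rescaled so the
#' six parameters are comparably conditioned).
#'
#' @param moving,fixed [BrainVolume-class] objects.
#' @param settings see [registrationSettings()].
#' @param init optional initial [RigidTransform-class]; overrides the
#'   moments-based initialisation when supplied.
#' @return list with `transform` (the recovered [RigidTransform-class]),
#'   `resampled` (moving resampled into the fixed frame), `converged`
#'   (FALSE if the iteration budget was exhausted; best-so-far is still
#'   returned) and `metricValue`.
#' @export
registerRigid <- function(moving, fixed, settings = registrationSettings(),
                          init = NULL) {
  stopifnot(is(moving, "BrainVolume"), is(fixed, "BrainVolume"))
  nl <- length(settings$shrinkFactors)
  pyr <- lapply(seq_len(nl), function(l) {
    f <- settings$shrinkFactors[l]
    list(fx = if (f > 1) .downsampleMeanC(fixed@data, f) else fixed@data,
         mv = if (f > 1) .downsampleMeanC(moving@data, f) else moving@data,
         fsp = fixed@spacing * f, msp = moving@spacing * f)
  })
  if (is.null(init)) {
    init <- if (settings$momentInit)
      momentInitTransform(pyr[[1]]$fx, pyr[[1]]$fsp, pyr[[1]]$mv,
                          pyr[[1]]$msp)
    else rigidTransform()
  }
  center <- init@center
  rs <- settings$rotScale
  par <- c(init@rotations / rs, init@translations)
  converged <- TRUE
  value <- NA_real_
  for (l in seq_len(nl)) {
    lv <- pyr[[l]]
    fn <- function(p) .rigidMsdC(lv$fx, lv$fsp, lv$mv, lv$msp, p[1:3] * rs,
                                 p[4:6], center)
    gr <- function(p) {
      g <- .rigidMsdGradC(lv$fx, lv$fsp, lv$mv, lv$msp, p[1:3] * rs,
                          p[4:6], center)$gradient
      c(g[1:3] * rs, g[4:6])
    }
    opt <- optim(par, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = settings$maxit[l], factr = 1e3))
    par <- opt$par
    value <- opt$value
    if (l == nl) converged <- opt$convergence == 0L
  }
  transform <- rigidTransform(par[1:3] * rs, par[4:6], center)
  resampled <- applyTransform(moving, transform, dim(fixed@data),
                              fixed@spacing)
  list(transform = transform, resampled = resampled, converged = converged,
       metricValue = value)
}

# Otsu threshold on a 256-bin histogram: maximises between-class variance.
otsuThreshold <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) stop("cannot threshold a constant volume")
  h <- tabulate(pmin(256L, as.integer((x - lo) / (hi - lo) * 256) + 1L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  muT <- mu[256]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  k <- which.max(sigmaB)
  lo + k / 256 * (hi - lo)
}

#' Brain extraction (skull stripping)
#'
#' Deterministic parenchyma isolation: voxels above an automatically chosen
#' (Otsu) intensity threshold are opened morphologically to detach the
#' scalp/skull shell, the largest 6-connected component is kept as brain,
#' and closing fills interior holes. The masked volume is input x mask.
#'
#' @param volume a [BrainVolume-class], registered to template space.
#' @param openRadius,closeRadius box structuring-element radii in voxels.
#' @return list with `mask` (integer 0/1 array) and `volume` (masked
#'   [BrainVolume-class]).
#' @export
extractBrain <- function(volume, openRadius = 1L, closeRadius = 2L) {
  stopifnot(is(volume, "BrainVolume"))
  x <- volume@data
  if (max(x) <= min(x))
    stop("brain extraction failed: volume is constant (empty mask)")
  th <- otsuThreshold(x)
  mask <- array(as.integer(x > th), dim = dim(x))
  if (openRadius > 0)
    mask <- .binDilateC(.binErodeC(mask, openRadius), openRadius)
  if (sum(mask) == 0L)
    stop("brain extraction failed: empty mask after thresholding")
  mask <- .largestComponentC(mask)
  if (closeRadius > 0)
    mask <- .binErodeC(.binDilateC(mask, closeRadius), closeRadius)
  masked <- brainVolume(x * mask, volume@spacing)
  list(mask = mask, volume = masked)
}

#' Two-step rigid alignment to a template
#'
#' The full alignment chain: (1) rigid registration of the input volume to
#' the template, (2) brain extraction of the registered volume, (3) rigid
#' registration of the skull-stripped result to the skull-stripped
#' template. The second pass refines the parenchyma alignment free of
#' scalp/skull influence.
#'
#' @param volume a [BrainVolume-class].
#' @param template a [BrainTemplate-class].
#' @param settings registration settings for the first (global) pass.
#' @param refineSettings settings for the second pass; the default starts
#'   from identity (the volume is already coarsely aligned) and searches
#'   only the finest pyramid level.
#' @return list with `volume` (the aligned, skull-stripped
#'   [BrainVolume-class] on the template grid), `transforms` (list of the
#'   two [RigidTransform-class] objects) and `converged`.
#' @export
twoStepAlign <- function(volume, template, settings = registrationSettings(),
                         refineSettings = NULL) {
  if (is.null(refineSettings))
    refineSettings <- registrationSettings(
      shrinkFactors = settings$shrinkFactors[length(settings$shrinkFactors)],
      maxit = settings$maxit[length(settings$maxit)], momentInit = FALSE)
  step1 <- registerRigid(volume, template@volume, settings)
  stripped <- extractBrain(step1$resampled)
  strippedTemplate <- brainVolume(template@volume@data * template@brainMask,
                                  template@volume@spacing)
  step2 <- registerRigid(stripped$volume, strippedTemplate, refineSettings)
  list(volume = step2$resampled,
       transforms = list(step1 = step1$transform, step2 = step2$transform),
       converged = step1$converged && step2$converged)
}

#' Extract the medial-temporal coronal slice stack
#'
#' Takes `nSlices` consecutive coronal planes (perpendicular to the
#' anterior-posterior axis) of a template-aligned volume, starting at the
#' template's anchor index and proceeding in `direction`
#' (posterior-to-anterior by default, covering the hippocampal body toward
#' the head), and min-max normalizes each slice.
#'
#' @param aligned a [BrainVolume-class] in template space.
#' @param template a [BrainTemplate-class].
#' @param nSlices number of slices (30 under the full-resolution 1 mm grid;
#'   choose `round(30 / spacing)` to keep the same 30 mm anatomical span).
#' @param direction "posterior-to-anterior" or "anterior-to-posterior".
#' @param subjectRef subject identifier stored in the stack.
#' @return A [SliceStack-class].
#' @export
extractCoronalSlices <- function(aligned, template, nSlices = 30L,
                                 direction = c("posterior-to-anterior",
                                               "anterior-to-posterior"),
                                 subjectRef = "subject") {
  direction <- match.arg(direction)
  stopifnot(is(aligned, "BrainVolume"), is(template, "BrainTemplate"))
  d <- dim(aligned@data)
  if (!identical(d, dim(template@volume@data)))
    stop("aligned volume must be on the template grid")
  anchor <- template@anchorIndex
  idx <- if (direction == "posterior-to-anterior")
    seq(anchor, anchor + nSlices - 1L) else seq(anchor, anchor - nSlices + 1L)
  if (min(idx) < 0L || max(idx) >= d[2])
    stop("slice range [", min(idx), ", ", max(idx), "] exceeds the grid")
  slices <- array(0, dim = c(d[1], d[3], nSlices))
  for (i in seq_len(nSlices))
    slices[, , i] <- minmaxNormalize(aligned@data[, idx[i] + 1L, ])
  new("SliceStack", slices = slices, sliceIndices = as.integer(idx),
      subjectRef = subjectRef)
}

#' @describeIn extractCoronalSlices number of slices in a stack.
#' @param stack a [SliceStack-class].
#' @export
nSlices <- function(stack) dim(stack@slices)[3]
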