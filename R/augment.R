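#' Augmentation configuration
#'
#' Parameter ranges for real-time stochastic slice augmentation during
#' training. Each range must contain its identity value (0 for rotation
#' and translation, 1 for scale, contrast and gamma); a degenerate range
#' disables that operation. Parameter draws come from the R RNG stream, so
#' augmentation is reproducible under the training seed.
#'
#' @param rotationDeg rotation range in degrees.
#' @param scale multiplicative scale range around 1.
#' @param translationPx translation range in pixels (drawn per axis).
#' @param contrast contrast-slope range around 1 (applied as
#'   c * (v - 0.5) + 0.5).
#' @param gamma gamma-exponent range around 1 (applied as v^gamma).
#' @return validated list of class `AugmentConfig`.
#' @export
augmentConfig <- function(rotationDeg = c(-10, 10), scale = c(0.9, 1.1),
                          translationPx = c(-8, 8), contrast = c(0.8, 1.2),
                          gamma = c(0.8, 1.2)) {
  cfg <- list(rotationDeg = rotationDeg, scale = scale,
              translationPx = translationPx, contrast = contrast,
              gamma = gamma)
  chk <- function(r, id, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] > id || r[2] < id)
      stop("range '", nm, "' must contain its identity value ", id)
  }
  chk(cfg$rotationDeg, 0, "rotationDeg")
  chk(cfg$scale, 1, "scale")
  chk(cfg$translationPx, 0, "translationPx")
  chk(cfg$contrast, 1, "contrast")
  chk(cfg$gamma, 1, "gamma")
  class(cfg) <- "AugmentConfig"
  cfg
}

#' Augment one normalized slice
#'
#' Applies, in fixed order, a geometric warp (rotation, scaling,
#' translation in one bilinear resampling pass with zero fill) followed by
#' intensity perturbations (contrast, then gamma), with every parameter
#' drawn uniformly from its configured range. The output is clipped to
#' [0, 1]. Deterministic given the RNG state.
#'
#' @param slice 2D array with values in [0, 1].
#' @param config an `AugmentConfig` (see [augmentConfig()]).
#' @return augmented 2D array of the same shape, values in [0, 1].
#' @export
augmentSlice <- function(slice, config = augmentConfig()) {
  if (min(slice) < -1e-6 || max(slice) > 1 + 1e-6)
    stop("augmentSlice expects a min-max normalized slice in [0, 1]")
  rot <- runif(1, config$rotationDeg[1], config$rotationDeg[2])
  sc <- runif(1, config$scale[1], config$scale[2])
  tx <- runif(1, config$translationPx[1], config$translationPx[2])
  ty <- runif(1, config$translationPx[1], config$translationPx[2])
  ct <- runif(1, config$contrast[1], config$contrast[2])
  gm <- runif(1, config$gamma[1], config$gamma[2])
  out <- .warpAffine2C(slice, rot, sc, tx, ty)
  out <- pmin(1, pmax(0, ct * (out - 0.5) + 0.5))
  out <- out^gm
  array(pmin(1, pmax(0, out)), dim = dim(slice))
}
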