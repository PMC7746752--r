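#' Create a rigid transform
#'
#' @param rotations Euler angles about x, y, z in degrees (applied as
#'   Rz Ry Rx).
#' @param translations translation in mm.
#' @param center rotation centre in mm (world origin is the volume centre).
#' @return A [RigidTransform-class].
#' @export
rigidTransform <- function(rotations = c(0, 0, 0), translations = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", rotations = as.numeric(rotations),
      translations = as.numeric(translations), center = as.numeric(center))
}

eulerMatrix <- function(rotDeg) {
  r <- rotDeg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  matrix(c(cz * cy, sz * cy, -sy,
           cz * sy * sx - sz * cx, sz * sy * sx + cz * cx, cy * sx,
           cz * sy * cx + sz * sx, sz * sy * cx - cz * sx, cy * cx),
         nrow = 3)  # columns of Rz Ry Rx
}

eulerFromMatrix <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock: fold everything into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Homogeneous 4x4 matrix of a rigid transform
#'
#' The linear part is a pure rotation, so its determinant is 1 — the
#' transform cannot scale or shear.
#'
#' @param transform a [RigidTransform-class].
#' @return 4x4 numeric matrix.
#' @export
transformMatrix <- function(transform) {
  R <- eulerMatrix(transform@rotations)
  c0 <- transform@center
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- c0 + transform@translations - R %*% c0
  m
}

matrixToTransform <- function(m, center = c(0, 0, 0)) {
  R <- m[1:3, 1:3]
  d <- m[1:3, 4]
  # solve d = c + t - R c for t
  t <- as.numeric(d - center + R %*% center)
  rigidTransform(eulerFromMatrix(R), t, center)
}

#' Compose two rigid transforms
#'
#' Returns the transform mapping p to `a(b(p))`; the set of rigid maps is
#' closed under composition.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return A [RigidTransform-class] with the centre of `a`.
#' @export
composeTransforms <- function(a, b) {
  matrixToTransform(transformMatrix(a) %*% transformMatrix(b), a@center)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  matrixToTransform(solve(transformMatrix(transform)), transform@center)
}

#' Deviation of a transform pair from identity
#'
#' Composes `a` with the inverse of `b` and reports the residual rotation
#' angle and translation magnitude; with `b` the ground-truth misalignment
#' and `a` the recovered transform this is the registration error.
#'
#' @param a recovered [RigidTransform-class].
#' @param b reference [RigidTransform-class] (default identity).
#' @return named numeric: `rotationDeg` (angle of the residual rotation)
#'   and `translationMm` (residual displacement at the centre).
#' @export
transformDeviation <- function(a, b = rigidTransform()) {
  e <- composeTransforms(a, invertTransform(b))
  R <- eulerMatrix(e@rotations)
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  c(rotationDeg = ang, translationMm = sqrt(sum(e@translations^2)))
}
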