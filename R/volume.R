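#' Create a brain volume
#'
#' @param data 3D numeric array in RAS axis order.
#' @param spacing voxel size in mm, length 1 (isotropic) or 3.
#' @return A [BrainVolume-class].
#' @export
brainVolume <- function(data, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  new("BrainVolume", data = data, spacing = as.numeric(spacing))
}

#' @describeIn brainVolume voxel data accessor.
#' @param volume a [BrainVolume-class].
#' @export
volData <- function(volume) volume@data

#' @describeIn brainVolume voxel spacing accessor (mm).
#' @export
voxelSpacing <- function(volume) volume@spacing

#' Resample a volume onto an isotropic cubic grid
#'
#' Trilinear interpolation onto a `grid`^3 lattice of `spacing` mm voxels;
#' the default reproduces the 256-voxel, 1 mm grid used for full-resolution
#' T1 volumes. The world-space centre is preserved and voxels falling
#' outside the input field of view are set to zero.
#'
#' @param volume a [BrainVolume-class].
#' @param grid voxels per axis of the output cube (default 256).
#' @param spacing isotropic output spacing in mm (default 1).
#' @return A resampled [BrainVolume-class].
#' @export
resampleIsotropic <- function(volume, grid = 256L, spacing = 1) {
  stopifnot(is(volume, "BrainVolume"))
  if (grid <= 0 || spacing <= 0) stop("grid and spacing must be positive")
  out <- .resampleRigidC(volume@data, volume@spacing,
                         as.integer(rep(grid, 3)), rep(spacing, 3),
                         c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  brainVolume(out, rep(spacing, 3))
}

#' Resample a moving volume through a rigid transform
#'
#' Samples the moving volume at `transform(p)` for every world point `p` of
#' the fixed grid (the resampling convention: the transform maps fixed-space
#' points into the moving volume).
#'
#' @param moving a [BrainVolume-class].
#' @param transform a [RigidTransform-class].
#' @param fixedDim output grid (default: the moving volume's own grid).
#' @param fixedSpacing output spacing (default: the moving volume's).
#' @return A [BrainVolume-class] on the fixed grid.
#' @export
applyTransform <- function(moving, transform, fixedDim = dim(moving@data),
                           fixedSpacing = moving@spacing) {
  out <- .resampleRigidC(moving@data, moving@spacing, as.integer(fixedDim),
                         as.numeric(fixedSpacing), transform@rotations,
                         transform@translations, transform@center)
  brainVolume(out, fixedSpacing)
}

#' Per-slice min-max normalization
#'
#' Rescales a 2D slice to [0, 1] as (v - min) / (max - min); a constant
#' slice maps to all zeros. Idempotent.
#'
#' @param slice 2D numeric array.
#' @return Normalized array of the same shape.
#' @export
minmaxNormalize <- function(slice) {
  if (any(!is.finite(slice))) stop("slice contains non-finite values")
  lo <- min(slice)
  hi <- max(slice)
  if (hi == lo) return(array(0, dim = dim(slice)))
  (slice - lo) / (hi - lo)
}

#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @return A [BrainVolume-class].
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")
  if (is.null(spacing)) spacing <- RNifti::pixdim(img)
  brainVolume(array(as.numeric(img), dim = dim(img)), spacing[1:3])
}

#' Write a volume as NIfTI-1
#'
#' The affine encodes the voxel spacing and RAS orientation with the origin
#' at the volume centre.
#'
#' @param volume a [BrainVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  d <- dim(volume@data)
  sp <- volume@spacing
  img <- structure(volume@data, pixdim = sp, pixunits = c("mm", "s"))
  img <- RNifti::asNifti(img)
  affine <- diag(c(sp, 1))
  affine[1:3, 4] <- -(d - 1) / 2 * sp
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
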