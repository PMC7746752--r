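#' Rigid spatial transform
#'
#' A 6-parameter rigid map between world coordinate frames:
#' \eqn{T(p) = R (p - c) + c + t}, where \eqn{R} is the rotation composed as
#' Rz Ry Rx from three Euler angles (degrees), \eqn{t} a translation (mm)
#' and \eqn{c} the rotation centre (mm). Used in the resampling convention:
#' a transform maps fixed-space points into the moving volume.
#'
#' @slot rotations numeric(3), Euler angles about x, y, z in degrees.
#' @slot translations numeric(3), translation in mm.
#' @slot center numeric(3), rotation centre in mm (world origin is the
#'   volume centre).
#' @export
setClass("RigidTransform",
  representation(rotations = "numeric", translations = "numeric",
                 center = "numeric"),
  prototype(rotations = c(0, 0, 0), translations = c(0, 0, 0),
            center = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  if (length(object@rotations) != 3L || length(object@translations) != 3L ||
      length(object@center) != 3L)
    return("rotations, translations and center must each have length 3")
  if (!all(is.finite(c(object@rotations, object@translations, object@center))))
    return("transform parameters must be finite")
  TRUE
})

#' 3D brain volume
#'
#' A scalar 3D image with isotropic-or-not voxel spacing. Arrays are stored
#' in RAS orientation (first axis left-to-right, second posterior-to-anterior,
#' third inferior-to-superior) with the world origin at the volume centre.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3), voxel size in mm per axis.
#' @slot orientation character, axis convention (always "RAS").
#' @export
setClass("BrainVolume",
  representation(data = "array", spacing = "numeric", orientation = "character"),
  prototype(orientation = "RAS"))

setValidity("BrainVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite values")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("data must be finite")
  TRUE
})

#' Registration template
#'
#' A population-average reference volume with its brain mask and the anchor
#' coronal index at which medial-temporal slice extraction starts.
#'
#' @slot volume a [BrainVolume-class], the template image.
#' @slot brainMask integer 3D array (0/1), brain parenchyma mask.
#' @slot anchorIndex integer, 0-based coronal (posterior-anterior axis)
#'   index of the start of the slice range.
#' @export
setClass("BrainTemplate",
  representation(volume = "BrainVolume", brainMask = "array",
                 anchorIndex = "integer"))

setValidity("BrainTemplate", function(object) {
  if (!identical(dim(object@brainMask), dim(object@volume@data)))
    return("brain mask shape must equal volume shape")
  n <- dim(object@volume@data)[2]
  if (object@anchorIndex < 0L || object@anchorIndex >= n)
    return("anchor index out of range")
  TRUE
})

#' Stack of normalized coronal slices
#'
#' The ordered set of min-max-normalized 2D coronal slices extracted for one
#' subject in template space; the unit fed to the slice classifier.
#'
#' @slot slices numeric array (H, W, n); each plane in [0, 1].
#' @slot sliceIndices integer(n), the 0-based coronal indices in template
#'   space, strictly consecutive.
#' @slot subjectRef character, subject identifier.
#' @export
setClass("SliceStack",
  representation(slices = "array", sliceIndices = "integer",
                 subjectRef = "character"))

setValidity("SliceStack", function(object) {
  d <- dim(object@slices)
  if (length(d) != 3L) return("slices must be a 3D array (H, W, n)")
  if (d[3] != length(object@sliceIndices))
    return("number of slices must match sliceIndices")
  if (min(object@slices) < -1e-9 || max(object@slices) > 1 + 1e-9)
    return("slice values must lie in [0, 1]")
  if (length(object@sliceIndices) > 1) {
    dd <- diff(object@sliceIndices)
    if (!(all(dd == 1L) || all(dd == -1L)))
      return("slice indices must be strictly consecutive")
  }
  TRUE
})

#' Trained slice classifier (one cross-validation fold)
#'
#' @slot weights list of parameter matrices/vectors.
#' @slot config classifier configuration (see [classifierConfig()]).
#' @slot bnStats running batch-normalisation statistics used at inference.
#' @slot history data.frame with one row per epoch (lr, train loss,
#'   validation loss, subject-level validation accuracy, decays applied).
#' @slot valSubjects character, subject ids of the fold's validation set.
#' @export
setClass("SliceClassifier",
  representation(weights = "list", config = "ANY", bnStats = "list",
                 history = "data.frame", valSubjects = "character"))

#' Ensemble of fold classifiers
#'
#' The k models produced by stratified k-fold cross-validation on one
#' development set; subject prediction averages their slice-averaged
#' probabilities.
#'
#' @slot models list of [SliceClassifier-class] objects.
#' @export
setClass("ClassifierEnsemble", representation(models = "list"))

setValidity("ClassifierEnsemble", function(object) {
  if (length(object@models) < 2L) return("ensemble needs at least 2 fold models")
  if (!all(vapply(object@models, is, logical(1), "SliceClassifier")))
    return("all members must be SliceClassifier objects")
  TRUE
})

#' ROC analysis result
#'
#' @slot thresholds numeric, swept decision thresholds.
#' @slot sensitivities numeric, sensitivity along the sweep.
#' @slot specificities numeric, specificity along the sweep.
#' @slot auc numeric, area under the curve (Mann-Whitney concordance,
#'   ties counted 1/2).
#' @slot aucVariance numeric, DeLong variance estimate of the AUC.
#' @slot scores numeric, the underlying prediction scores.
#' @slot labels integer, the underlying labels (1 = AD, 0 = CN).
#' @export
setClass("ROCResult",
  representation(thresholds = "numeric", sensitivities = "numeric",
                 specificities = "numeric", auc = "numeric",
                 aucVariance = "numeric", scores = "numeric",
                 labels = "integer"))

setValidity("ROCResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must be in [0, 1]")
  if (!is.na(object@aucVariance) && object@aucVariance < 0)
    return("aucVariance must be non-negative")
  TRUE
})

#' Operating point chosen by Youden's index
#'
#' @slot threshold numeric decision threshold (predict AD when score >=
#'   threshold).
#' @slot sensitivity,specificity,accuracy numeric in [0, 1].
#' @slot youdenJ numeric, sensitivity + specificity - 1.
#' @export
setClass("OperatingPoint",
  representation(threshold = "numeric", sensitivity = "numeric",
                 specificity = "numeric", accuracy = "numeric",
                 youdenJ = "numeric"))

#' Hypothesis test result
#'
#' @slot statistic numeric test statistic (t, z or chi-square).
#' @slot df numeric degrees of freedom (NA where not applicable).
#' @slot pValue numeric two-sided p-value.
#' @slot method character description.
#' @export
setClass("TestStatistic",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 method = "character"))

setValidity("TestStatistic", function(object) {
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("p-value must be in [0, 1]")
  TRUE
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n",
      "  rotations (deg): ", paste(signif(object@rotations, 4), collapse = ", "), "\n",
      "  translations (mm): ", paste(signif(object@translations, 4), collapse = ", "), "\n",
      "  center (mm): ", paste(signif(object@center, 4), collapse = ", "), "\n", sep = "")
})

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat("BrainVolume ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(object@spacing, collapse = " x "), " mm (", object@orientation,
      ")\n", sep = "")
})

setMethod("show", "BrainTemplate", function(object) {
  cat("BrainTemplate on ", paste(dim(object@volume@data), collapse = " x "),
      " grid; anchor coronal index ", object@anchorIndex, "; mask ",
      sum(object@brainMask), " voxels\n", sep = "")
})

setMethod("show", "SliceStack", function(object) {
  d <- dim(object@slices)
  cat("SliceStack '", object@subjectRef, "': ", d[3], " slices of ", d[1],
      " x ", d[2], ", coronal indices ", object@sliceIndices[1], "..",
      object@sliceIndices[d[3]], "\n", sep = "")
})

setMethod("show", "SliceClassifier", function(object) {
  cat("SliceClassifier (", object@config$backbone, ", featureDim ",
      object@config$featureDim, "), trained ", nrow(object@history),
      " epochs, best val accuracy ",
      signif(max(object@history$valAccuracy), 3), "\n", sep = "")
})

setMethod("show", "ClassifierEnsemble", function(object) {
  cat("ClassifierEnsemble of", length(object@models), "fold models\n")
})

setMethod("show", "ROCResult", function(object) {
  cat("ROCResult: AUC ", signif(object@auc, 4), " (DeLong SE ",
      signif(sqrt(object@aucVariance), 3), "), n = ", length(object@scores),
      "\n", sep = "")
})

setMethod("show", "TestStatistic", function(object) {
  cat(object@method, ": statistic ", signif(object@statistic, 4),
      if (!is.na(object@df)) paste0(", df ", signif(object@df, 4)) else "",
      ", p ", signif(object@pValue, 3), "\n", sep = "")
})
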