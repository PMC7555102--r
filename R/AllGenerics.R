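## Generics and accessors. Slots are never touched directly by user code.

#' Volume of a binary mask in cubic millimetres
#'
#' Voxel count times the absolute determinant of the linear part of the
#' voxel-to-world affine.
#'
#' @param x A [SeedROI-class] or [MPMask-class].
#' @return Scalar volume in mm^3 (0 for an empty mask).
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' Center of gravity of a binary map, in template mm coordinates
#'
#' The unweighted mean of the centers of all mask voxels, mapped through the
#' affine. A probability-weighted variant is available for sensitivity
#' checks via `weights`.
#'
#' @param x A [MPMask-class], [SeedROI-class], or logical array (with
#'   `affine` supplied).
#' @param ... Further arguments; see methods.
#' @return Named numeric vector c(x, y, z) in mm.
#' @export
setGeneric("centerOfGravity", function(x, ...) standardGeneric("centerOfGravity"))

#' @rdname accessors
#' @export
setGeneric("affineMM", function(x) standardGeneric("affineMM"))

#' @rdname accessors
#' @export
setGeneric("seedMask", function(x) standardGeneric("seedMask"))

#' @rdname accessors
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' @rdname accessors
#' @export
setGeneric("parcelLabels", function(x) standardGeneric("parcelLabels"))

#' @rdname accessors
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("fractionValues", function(x) standardGeneric("fractionValues"))

#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("targetLabel", function(x) standardGeneric("targetLabel"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname accessors
#' @export
setGeneric("truthParcellation", function(x) standardGeneric("truthParcellation"))

#' @rdname accessors
#' @export
setGeneric("cohortConfigOf", function(x) standardGeneric("cohortConfigOf"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Accessors for pallidoparc objects
#'
#' Read-only access to the slots of the S4 containers: `affineMM` (4x4
#' voxel-to-world matrix), `seedMask` (logical seed array), `labelNames`,
#' `parcelLabels` (integer label array), `densityValues`, `maskArray`,
#' `fractionValues`, `subjectID`, `targetLabel`, `isNormalized`,
#' `subjects` (list of subject bundles), `truthParcellation`,
#' `cohortConfigOf`, and `provenance` (metadata list).
#'
#' @param x A pallidoparc S4 object.
#' @return The slot value; see each generic.
#' @name accessors
NULL

setMethod("affineMM", "SeedROI", function(x) x@affine)
setMethod("affineMM", "DensityMap", function(x) x@affine)
setMethod("affineMM", "LabelParcellation", function(x) x@affine)
setMethod("affineMM", "ProbabilityMap", function(x) x@affine)
setMethod("affineMM", "MPMask", function(x) x@affine)

setMethod("seedMask", "SeedROI", function(x) x@mask)
setMethod("seedMask", "DensityMap", function(x) x@seedROI)
setMethod("seedMask", "LabelParcellation", function(x) x@seedROI)
setMethod("seedMask", "Cohort", function(x) x@seedROI@mask)
setMethod("seedMask", "SubjectBundle", function(x) x@seedROI@mask)

setMethod("labelNames", "LabelParcellation", function(x) x@labelNames)
setMethod("labelNames", "CohortConfig", function(x) x@labelNames)
setMethod("labelNames", "Cohort", function(x) x@config@labelNames)

setMethod("parcelLabels", "LabelParcellation", function(x) x@labels)
setMethod("densityValues", "DensityMap", function(x) x@values)
setMethod("maskArray", "MPMask", function(x) x@mask)
setMethod("maskArray", "SeedROI", function(x) x@mask)
setMethod("fractionValues", "ProbabilityMap", function(x) x@fraction)

setMethod("subjectID", "DensityMap", function(x) x@subjectID)
setMethod("subjectID", "SubjectBundle", function(x) x@subjectID)
setMethod("targetLabel", "DensityMap", function(x) x@targetLabel)
setMethod("isNormalized", "DensityMap", function(x) x@normalized)

setMethod("subjects", "Cohort", function(x) x@subjects)
setMethod("truthParcellation", "Cohort", function(x) x@truth)
setMethod("truthParcellation", "SubjectBundle", function(x) x@truth)
setMethod("cohortConfigOf", "Cohort", function(x) x@config)
setMethod("provenance", "LabelParcellation", function(x) x@metadata)

#' @describeIn accessors Density maps of one subject (named list).
#' @export
subjectDensities <- function(x) {
  stopifnot(methods::is(x, "SubjectBundle"))
  x@densities
}
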