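## S4 classes for the volumetric objects moved through the parcellation
## pipeline. All volumes carry a 4x4 RAS affine (0-based voxel -> mm).

#' CohortConfig: parameters of the synthetic pallidal cohort
#'
#' Describes the study conditions a synthetic cohort is generated under:
#' grid geometry, the anteroposterior topographic gradient of target
#' dominance, and the per-subject noise/jitter model. The gradient places one
#' Gaussian density profile per target along one axis; with the canonical
#' four functional territories the ordering is limbic, associative,
#' sensorimotor, other from anterior to posterior.
#'
#' @slot nSubjects Number of subjects in the cohort.
#' @slot gridShape Integer grid dimensions (voxels).
#' @slot voxelSizeMM Isotropic voxel size in mm.
#' @slot nTargets Number of connectivity targets (>= 2).
#' @slot gradientAxis One of "x", "y", "z"; the topographic axis.
#' @slot gradientCenters Normalized peak positions in [0,1], strictly
#'   increasing, one per target.
#' @slot gradientWidth Gaussian width of each density profile (normalized
#'   units of the seed-ROI extent along the gradient axis).
#' @slot noiseCV Coefficient of variation of the multiplicative log-normal
#'   voxel noise (0 disables noise).
#' @slot jitterSDmm SD (mm) of the per-subject rigid translation of the
#'   gradient along its axis (0 disables jitter).
#' @slot roiHalfAxes Half-axes of the ellipsoidal seed ROI, in voxels.
#' @slot labelNames Target names, anterior to posterior.
#' @slot rngSeed Integer seed making the whole cohort reproducible.
#' @export
setClass("CohortConfig", representation(
  nSubjects = "integer", gridShape = "integer", voxelSizeMM = "numeric",
  nTargets = "integer", gradientAxis = "character",
  gradientCenters = "numeric", gradientWidth = "numeric",
  noiseCV = "numeric", jitterSDmm = "numeric", roiHalfAxes = "numeric",
  labelNames = "character", rngSeed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (length(object@gridShape) != 3L || any(object@gridShape < 5L))
    msg <- c(msg, "configuration error: gridShape must be 3 dimensions, each >= 5")
  if (object@voxelSizeMM <= 0) msg <- c(msg, "voxelSizeMM must be positive")
  if (object@nTargets < 2L)
    msg <- c(msg, "configuration error: nTargets must be >= 2")
  if (!object@gradientAxis %in% c("x", "y", "z"))
    msg <- c(msg, "gradientAxis must be one of x, y, z")
  if (length(object@gradientCenters) != object@nTargets)
    msg <- c(msg, "gradientCenters must have one entry per target")
  if (any(diff(object@gradientCenters) <= 0))
    msg <- c(msg, "gradientCenters must be strictly increasing (anteroposterior ordering)")
  if (any(object@gradientCenters < 0) || any(object@gradientCenters > 1))
    msg <- c(msg, "gradientCenters must lie in [0,1]")
  if (object@gradientWidth <= 0) msg <- c(msg, "gradientWidth must be positive")
  if (object@noiseCV < 0) msg <- c(msg, "noiseCV must be nonnegative")
  if (object@jitterSDmm < 0) msg <- c(msg, "jitterSDmm must be nonnegative")
  if (length(object@roiHalfAxes) != 3L || any(object@roiHalfAxes <= 0))
    msg <- c(msg, "roiHalfAxes must be 3 positive values")
  if (length(object@labelNames) != object@nTargets)
    msg <- c(msg, "labelNames must have one entry per target")
  if (length(msg)) msg else TRUE
})

#' SeedROI: binary seed mask with geometry
#'
#' @slot mask Logical 3D array, TRUE inside the seed region.
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("SeedROI", representation(mask = "array", affine = "matrix"))

setValidity("SeedROI", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical array")
  if (length(dim(object@mask)) != 3L) return("mask must be 3-dimensional")
  if (!identical(dim(object@affine), c(4L, 4L))) return("affine must be 4x4")
  TRUE
})

#' DensityMap: connectivity density from one seed to one target
#'
#' A track-density volume restricted to a seed ROI: the evidence a seed voxel
#' has for being connected to one target. Values are nonnegative and zero
#' outside the ROI. `normalized` records whether the map has been divided by
#' its mean in-ROI intensity (the step making maps of different targets
#' comparable before winner-takes-all segmentation).
#'
#' @slot values Numeric 3D array of densities.
#' @slot seedROI Logical 3D array delimiting the seed region.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot targetLabel Name of the connectivity target.
#' @slot subjectID Subject identifier.
#' @slot normalized Logical flag set by [normalizeDensity()].
#' @export
setClass("DensityMap", representation(
  values = "array", seedROI = "array", affine = "matrix",
  targetLabel = "character", subjectID = "character",
  normalized = "logical"))

setValidity("DensityMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@seedROI)))
    msg <- c(msg, "values and seedROI must share one grid")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (any(object@values < 0)) msg <- c(msg, "values must be nonnegative")
  if (any(object@values[!object@seedROI] != 0))
    msg <- c(msg, "values must be zero outside the seed ROI")
  if (length(msg)) msg else TRUE
})

#' LabelParcellation: hard segmentation of a seed ROI
#'
#' Integer label field produced by winner-takes-all segmentation: 0 means
#' unlabeled (no positive density under any target), 1..K indexes
#' `labelNames`. Each voxel carries at most one label.
#'
#' @slot labels Integer 3D array of labels.
#' @slot labelNames Ordered target names (index i is label i).
#' @slot seedROI Logical 3D array delimiting the seed region.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot metadata Provenance list (subject, nucleus, pathway, stage-1
#'   targets, tracking parameters).
#' @export
setClass("LabelParcellation", representation(
  labels = "array", labelNames = "character", seedROI = "array",
  affine = "matrix", metadata = "list"))

setValidity("LabelParcellation", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), dim(object@seedROI)))
    msg <- c(msg, "labels and seedROI must share one grid")
  lab <- object@labels
  if (any(lab < 0L) || any(lab > length(object@labelNames)))
    msg <- c(msg, "labels must lie in 0..K with K = length(labelNames)")
  if (any(lab[!object@seedROI] != 0L))
    msg <- c(msg, "labels must be zero outside the seed ROI")
  if (length(msg)) msg else TRUE
})

#' ProbabilityMap: per-voxel fraction of subjects covered by one label
#'
#' @slot fraction Numeric 3D array in [0,1].
#' @slot labelName Which label the fractions refer to.
#' @slot nSubjects Number of subjects aggregated.
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("ProbabilityMap", representation(
  fraction = "array", labelName = "character", nSubjects = "integer",
  affine = "matrix"))

setValidity("ProbabilityMap", function(object) {
  msg <- character()
  if (any(object@fraction < 0) || any(object@fraction > 1))
    msg <- c(msg, "fractions must lie in [0,1]")
  counts <- object@fraction * object@nSubjects
  if (max(abs(counts - round(counts))) > 1e-6)
    msg <- c(msg, "fraction x nSubjects must be integral")
  if (length(msg)) msg else TRUE
})

#' MPMask: thresholded maximum probability map
#'
#' Binary group map retaining the voxels covered by a label in at least a
#' given fraction of the sample (the population threshold; 0.5 keeps voxels
#' overlapping in at least half of the subjects).
#'
#' @slot mask Logical 3D array.
#' @slot labelName Label the mask represents.
#' @slot thresholdFraction Population threshold in (0,1].
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("MPMask", representation(
  mask = "array", labelName = "character", thresholdFraction = "numeric",
  affine = "matrix"))

setValidity("MPMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (object@thresholdFraction <= 0 || object@thresholdFraction > 1)
    msg <- c(msg, "thresholdFraction must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' SubjectBundle: one subject's synthetic data with ground truth
#'
#' @slot subjectID Subject identifier.
#' @slot seedROI SeedROI shared by all density maps of the subject.
#' @slot densities Named list of [DensityMap-class], one per target.
#' @slot truth [LabelParcellation-class] giving the noiseless generating
#'   labels (argmax of the jitter-free profiles).
#' @export
setClass("SubjectBundle", representation(
  subjectID = "character", seedROI = "SeedROI", densities = "list",
  truth = "LabelParcellation"))

#' Cohort: a simulated multi-subject dataset
#'
#' @slot config The [CohortConfig-class] that generated the cohort.
#' @slot seedROI Shared template-space seed ROI.
#' @slot truth Shared ground-truth parcellation (identical across subjects;
#'   jitter translates profiles, not the ROI).
#' @slot subjects List of [SubjectBundle-class].
#' @export
setClass("Cohort", representation(
  config = "CohortConfig", seedROI = "SeedROI",
  truth = "LabelParcellation", subjects = "list"))

#' PermutationResult: paired sign-flip permutation test with t-max correction
#'
#' @slot variables Variable (parcel) names tested.
#' @slot tObs Observed paired t statistic per variable (NA when undefined).
#' @slot pCorrected t-max familywise-corrected two-sided p per variable.
#' @slot pUncorrected Per-variable (uncorrected) permutation p.
#' @slot excluded Logical, variables excluded from the max statistic
#'   (degenerate zero-variance differences with nonzero mean).
#' @slot nPerm Number of permutations (or 2^n when exhaustive).
#' @slot exact TRUE when all sign patterns were enumerated.
#' @slot alpha Nominal familywise level.
#' @slot rngSeed Seed used for Monte-Carlo sign flips.
#' @export
setClass("PermutationResult", representation(
  variables = "character", tObs = "numeric", pCorrected = "numeric",
  pUncorrected = "numeric", excluded = "logical", nPerm = "integer",
  exact = "logical", alpha = "numeric", rngSeed = "integer"))

#' ProximityReport: distances and membership of sites versus maps
#'
#' @slot distances Matrix (maps x sites) of Euclidean distances in mm
#'   between map centers of gravity and site coordinates.
#' @slot membership Character matrix (maps x sites), "inside"/"outside", or
#'   a 0x0 matrix when no masks were supplied.
#' @slot ranking Named list per site: map names ordered by increasing
#'   distance.
#' @slot nearest Named character vector: nearest map per site.
#' @export
setClass("ProximityReport", representation(
  distances = "matrix", membership = "matrix", ranking = "list",
  nearest = "character"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nSubjects, "subjects,",
      paste(object@gridShape, collapse = "x"), "grid @",
      object@voxelSizeMM, "mm\n")
  cat("  targets:", paste(object@labelNames, collapse = ", "),
      "along", object@gradientAxis, "\n")
  cat(sprintf("  centers: %s  width: %.3g  noiseCV: %.3g  jitterSD: %.3g mm  seed: %d\n",
              paste(signif(object@gradientCenters, 3), collapse = ", "),
              object@gradientWidth, object@noiseCV, object@jitterSDmm,
              object@rngSeed))
})

setMethod("show", "SeedROI", function(object) {
  cat("SeedROI:", sum(object@mask), "voxels (",
      format(maskVolume(object), digits = 6), "mm^3 ) on",
      paste(dim(object@mask), collapse = "x"), "grid\n")
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap [%s -> %s]%s: %d ROI voxels, mean in-ROI %.4g\n",
              object@subjectID, object@targetLabel,
              if (isTRUE(object@normalized)) " (normalized)" else "",
              sum(object@seedROI),
              mean(object@values[object@seedROI])))
})

setMethod("show", "LabelParcellation", function(object) {
  tab <- tabulate(object@labels[object@seedROI] + 1L,
                  nbins = length(object@labelNames) + 1L)
  cat("LabelParcellation:", paste(dim(object@labels), collapse = "x"),
      "grid,", sum(object@seedROI), "ROI voxels\n")
  cat("  unlabeled:", tab[1L], "\n")
  for (i in seq_along(object@labelNames))
    cat("  ", object@labelNames[i], ":", tab[i + 1L], "\n")
})

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf("ProbabilityMap [%s]: n=%d subjects, %d voxels with fraction > 0\n",
              object@labelName, object@nSubjects, sum(object@fraction > 0)))
})

setMethod("show", "MPMask", function(object) {
  cat(sprintf("MPMask [%s] @ %.0f%% threshold: %d voxels (%.4g mm^3)\n",
              object@labelName, 100 * object@thresholdFraction,
              sum(object@mask), maskVolume(object)))
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort of", length(object@subjects), "subjects\n")
  show(object@config)
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: %d variables, %s%d permutations, alpha=%.3g\n",
              length(object@variables),
              if (object@exact) "exhaustive " else "", object@nPerm,
              object@alpha))
  df <- data.frame(variable = object@variables,
                   t = signif(object@tObs, 4),
                   p.corrected = signif(object@pCorrected, 4),
                   sig = ifelse(!is.na(object@pCorrected) &
                                object@pCorrected < object@alpha, "*", ""))
  print(df, row.names = FALSE)
})

setMethod("show", "ProximityReport", function(object) {
  cat("ProximityReport:", nrow(object@distances), "maps x",
      ncol(object@distances), "sites (mm)\n")
  print(round(object@distances, 2))
})
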