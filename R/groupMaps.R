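## Group-level aggregation: probability maps over subjects, thresholded
## maximum probability maps (MPMs), volumes and centers of gravity.

#' Binary mask of one parcel of a parcellation
#'
#' @param parcellation A [LabelParcellation-class].
#' @param label Label name (must appear in `labelNames(parcellation)`).
#' @return An [MPMask-class] with `thresholdFraction = 1` carrying the
#'   subject-level parcel (a convenience container; no thresholding is
#'   involved at subject level).
#' @export
parcelMask <- function(parcellation, label) {
  idx <- match(label, labelNames(parcellation))
  if (is.na(idx))
    stop(sprintf("key error: unknown label '%s' (have: %s)", label,
                 paste(labelNames(parcellation), collapse = ", ")))
  methods::new("MPMask", mask = parcelLabels(parcellation) == idx,
               labelName = label, thresholdFraction = 1,
               affine = affineMM(parcellation))
}

#' Per-voxel fraction of subjects whose parcel covers the voxel
#'
#' Subject parcels for `label` are binarized and summed; the per-voxel
#' fraction is the count divided by the number of subjects. All
#' parcellations must live on one (template) grid.
#'
#' @param parcels List of [LabelParcellation-class], one per subject.
#' @param label Label name.
#' @return A [ProbabilityMap-class].
#' @export
buildProbabilityMap <- function(parcels, label) {
  stopifnot(is.list(parcels), length(parcels) >= 1L)
  ref <- parcels[[1L]]
  idx <- match(label, labelNames(ref))
  if (is.na(idx))
    stop(sprintf("key error: unknown label '%s' (have: %s)", label,
                 paste(labelNames(ref), collapse = ", ")))
  acc <- array(0, dim(parcelLabels(ref)))
  for (p in parcels) {
    checkSameGrid(parcelLabels(p), parcelLabels(ref), "subject parcellations")
    acc <- acc + (parcelLabels(p) == idx)
  }
  methods::new("ProbabilityMap", fraction = acc / length(parcels),
               labelName = label, nSubjects = length(parcels),
               affine = affineMM(ref))
}

#' Threshold a probability map into a maximum probability map
#'
#' Retains voxels covered in at least `thresholdFraction` of the sample;
#' the comparison is inclusive (>=), so at threshold 0.5 a voxel present in
#' exactly half of the subjects is kept.
#'
#' @param pmap A [ProbabilityMap-class].
#' @param thresholdFraction Population threshold in (0,1]; default 0.5.
#' @return An [MPMask-class].
#' @export
thresholdMPM <- function(pmap, thresholdFraction = 0.5) {
  stopifnot(methods::is(pmap, "ProbabilityMap"))
  if (thresholdFraction <= 0 || thresholdFraction > 1)
    stop("thresholdFraction must lie in (0,1]")
  fr <- fractionValues(pmap)
  mask <- array(fr >= thresholdFraction - 1e-12, dim(fr))
  methods::new("MPMask", mask = mask, labelName = pmap@labelName,
               thresholdFraction = thresholdFraction, affine = affineMM(pmap))
}

#' @describeIn maskVolume Volume of a thresholded MPM.
setMethod("maskVolume", "MPMask", function(x) {
  if (abs(det(affineMM(x))) < .Machine$double.eps)
    stop("geometry error: singular affine")
  sum(maskArray(x)) * voxelVolumeMM3(affineMM(x))
})

#' @describeIn maskVolume Volume of a seed ROI.
setMethod("maskVolume", "SeedROI", function(x) {
  if (abs(det(affineMM(x))) < .Machine$double.eps)
    stop("geometry error: singular affine")
  sum(maskArray(x)) * voxelVolumeMM3(affineMM(x))
})

cogOfMask <- function(mask, affine, weights = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("value error: empty mask has no center of gravity")
  if (is.null(weights)) {
    ctr <- colMeans(idx)
  } else {
    w <- weights[mask]
    if (sum(w) <= 0) stop("value error: nonpositive total weight")
    ctr <- colSums(idx * w) / sum(w)
  }
  out <- drop(voxelToWorldMM(affine, ctr))
  names(out) <- c("x", "y", "z")
  out
}

#' @describeIn centerOfGravity Unweighted centroid of a thresholded MPM; set
#'   `weights` to a [ProbabilityMap-class] for the probability-weighted
#'   variant (a sensitivity option, not the default).
#' @param weights Optional [ProbabilityMap-class] supplying voxel weights.
setMethod("centerOfGravity", "MPMask", function(x, weights = NULL) {
  w <- if (is.null(weights)) NULL else fractionValues(weights)
  cogOfMask(maskArray(x), affineMM(x), w)
})

#' @describeIn centerOfGravity Centroid of a seed ROI.
setMethod("centerOfGravity", "SeedROI", function(x) {
  cogOfMask(maskArray(x), affineMM(x))
})

#' Group maps for every label of a set of subject parcellations
#'
#' @param parcels List of [LabelParcellation-class], one per subject.
#' @param thresholdFraction Population threshold (default 0.5).
#' @return Named list per label: `list(pmap = ProbabilityMap, mpm = MPMask)`.
#' @export
buildGroupMaps <- function(parcels, thresholdFraction = 0.5) {
  labs <- labelNames(parcels[[1L]])
  out <- lapply(labs, function(lab) {
    pm <- buildProbabilityMap(parcels, lab)
    list(pmap = pm, mpm = thresholdMPM(pm, thresholdFraction))
  })
  names(out) <- labs
  out
}

#' Volume and COG table for a set of MPMs
#'
#' One row per map with full provenance keys, mirroring an atlas summary
#' table (volumes in mm^3, COG in template mm coordinates).
#'
#' @param mpms Named list of [MPMask-class] (names become the label column
#'   when the masks carry no label).
#' @param nucleus,pathway,hemisphere Provenance keys recycled across rows.
#' @return data.frame with columns nucleus, pathway, label, hemisphere,
#'   n_voxels, volume_mm3, cog_x, cog_y, cog_z.
#' @export
mpmTable <- function(mpms, nucleus = NA_character_, pathway = NA_character_,
                     hemisphere = NA_character_) {
  rows <- lapply(seq_along(mpms), function(i) {
    m <- mpms[[i]]
    nvox <- sum(maskArray(m))
    cog <- if (nvox > 0) centerOfGravity(m) else c(x = NA_real_,
                                                   y = NA_real_,
                                                   z = NA_real_)
    data.frame(nucleus = nucleus, pathway = pathway,
               label = m@labelName, hemisphere = hemisphere,
               n_voxels = nvox, volume_mm3 = if (nvox > 0) maskVolume(m) else 0,
               cog_x = cog[["x"]], cog_y = cog[["y"]], cog_z = cog[["z"]])
  })
  do.call(rbind, rows)
}
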