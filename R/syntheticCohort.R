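## Synthetic multi-subject cohort generator. Densities follow Gaussian
## profiles along one (anteroposterior) axis with multiplicative log-normal
## voxel noise and a per-subject rigid translation (jitter) of the profiles;
## the ground-truth labels are the argmax of the noiseless, jitter-free
## profiles and are therefore known analytically.

#' Construct a synthetic cohort configuration
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: 20 subjects on a 16x30x14 grid of 1 mm template voxels with an
#' ellipsoidal seed ROI elongated along the anteroposterior (y) axis
#' (half-axes 6/13/5 mm, about 1.6 cm^3 -- the scale of the combined
#' pallidal segments), four targets (limbic, associative, sensorimotor,
#' other) peaking at normalized positions 0.15/0.40/0.65/0.90, profile
#' width 0.06, 30% multiplicative noise and 0.5 mm (half-voxel)
#' translation jitter.
#'
#' @param nSubjects Number of subjects.
#' @param gridShape Grid dimensions in voxels (each >= 5).
#' @param voxelSizeMM Isotropic voxel size (mm).
#' @param nTargets Number of targets (>= 2).
#' @param gradientAxis Topographic axis, "x", "y" or "z".
#' @param gradientCenters Strictly increasing normalized peak positions.
#' @param gradientWidth Gaussian width (normalized units).
#' @param noiseCV CV of the multiplicative log-normal voxel noise.
#' @param jitterSDmm SD (mm) of the per-subject profile translation.
#' @param roiHalfAxes Ellipsoid half-axes in voxels.
#' @param labelNames Target names (anterior to posterior).
#' @param rngSeed Integer RNG seed.
#' @return A validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(nSubjects = 3, noiseCV = 0)
#' cfg
#' @export
cohortConfig <- function(nSubjects = 20L,
                         gridShape = c(16L, 30L, 14L),
                         voxelSizeMM = 1.0,
                         nTargets = 4L,
                         gradientAxis = "y",
                         gradientCenters = c(0.15, 0.40, 0.65, 0.90),
                         gradientWidth = 0.06,
                         noiseCV = 0.3,
                         jitterSDmm = 0.5,
                         roiHalfAxes = c(6, 13, 5),
                         labelNames = NULL,
                         rngSeed = 42L) {
  if (is.null(labelNames)) {
    canonical <- c("limbic", "associative", "sensorimotor", "other")
    labelNames <- if (nTargets == 4L) canonical else
      paste0("target", seq_len(nTargets))
  }
  methods::new("CohortConfig",
    nSubjects = as.integer(nSubjects), gridShape = as.integer(gridShape),
    voxelSizeMM = voxelSizeMM, nTargets = as.integer(nTargets),
    gradientAxis = gradientAxis, gradientCenters = gradientCenters,
    gradientWidth = gradientWidth, noiseCV = noiseCV,
    jitterSDmm = jitterSDmm, roiHalfAxes = roiHalfAxes,
    labelNames = labelNames, rngSeed = as.integer(rngSeed))
}

#' Build the ellipsoidal seed ROI of a configuration
#'
#' The ROI is an axis-aligned ellipsoid centered in the grid, a connected
#' convex stand-in for a pallidal segment mask. The affine centers the grid
#' at the world origin with isotropic scaling.
#'
#' @param config A [CohortConfig-class].
#' @return A [SeedROI-class]; its volume in mm^3 is available via
#'   [maskVolume()].
#' @examples
#' roi <- makeSeedROI(cohortConfig())
#' maskVolume(roi)
#' @export
makeSeedROI <- function(config) {
  methods::validObject(config)
  dims <- config@gridShape
  ctr <- (dims + 1) / 2
  ha <- config@roiHalfAxes
  idx <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
  r2 <- ((idx$i - ctr[1]) / ha[1])^2 + ((idx$j - ctr[2]) / ha[2])^2 +
        ((idx$k - ctr[3]) / ha[3])^2
  mask <- array(r2 <= 1, dim = dims)
  if (sum(mask) < 100L)
    stop("configuration error: seed ROI smaller than 100 voxels; ",
         "enlarge gridShape or roiHalfAxes")
  methods::new("SeedROI", mask = mask,
               affine = isotropicAffine(dims, config@voxelSizeMM))
}

## Normalized position of each voxel along the gradient axis, relative to
## the ROI bounding box (0 at the anterior edge, 1 at the posterior edge).
gradientPositions <- function(mask, axis) {
  ax <- axisIndex(axis)
  dims <- dim(mask)
  present <- apply(mask, ax, any)
  rng <- range(which(present))
  coord <- slice.index(array(0, dims), ax)
  (coord - rng[1]) / (rng[2] - rng[1])
}

## Gaussian profile matrix: rows = voxels (vector p), cols = targets.
profileMatrix <- function(p, centers, width, widthMult = NULL) {
  K <- length(centers)
  if (is.null(widthMult)) widthMult <- rep(1, K)
  vapply(seq_len(K), function(t) {
    w <- width * widthMult[t]
    exp(-(p - centers[t])^2 / (2 * w^2))
  }, numeric(length(p)))
}

## Row-wise argmax with ties broken by lowest column index.
argmaxFirst <- function(m) {
  max.col(m, ties.method = "first")
}

#' Simulate a multi-subject cohort of target density maps
#'
#' For each subject, the density of target t at voxel v is
#' `G_t(pos(v) + jitter) * eps(v)`, where `G_t` is a Gaussian profile along
#' the gradient axis, `jitter` a subject-level translation drawn from
#' `N(0, jitterSDmm)`, and `eps` log-normal noise with unit mean and the
#' configured coefficient of variation. Densities are zero outside the seed
#' ROI. The ground truth is the per-voxel argmax of the noiseless,
#' jitter-free profiles, identical for all subjects.
#'
#' @param config A [CohortConfig-class].
#' @param widthMult Optional per-target multiplier of the profile width
#'   (used to plant hemispheric effects; default all 1).
#' @return A [Cohort-class] whose subjects each carry density maps and the
#'   shared truth parcellation.
#' @examples
#' coh <- simulateCohort(cohortConfig(nSubjects = 2, noiseCV = 0,
#'                                    jitterSDmm = 0))
#' truthParcellation(coh)
#' @export
simulateCohort <- function(config, widthMult = NULL) {
  methods::validObject(config)
  roi <- makeSeedROI(config)
  mask <- roi@mask
  dims <- dim(mask)
  inROI <- which(mask)
  pos <- gradientPositions(mask, config@gradientAxis)[inROI]

  ## Truth is the noiseless, jitter-free winner under the same
  ## mean-intensity normalization the segmentation applies: dividing each
  ## profile by its mean in-ROI value preserves the contiguous-slab
  ## structure (log-ratios stay monotone along the gradient) but places
  ## the boundaries exactly where an ideal noise-free subject's
  ## winner-takes-all parcellation places them.
  Gtruth <- profileMatrix(pos, config@gradientCenters, config@gradientWidth,
                          widthMult)
  Gtruth <- sweep(Gtruth, 2L, colMeans(Gtruth), "/")
  truthLab <- integer(length(mask))
  truthLab[inROI] <- argmaxFirst(Gtruth)
  truth <- methods::new("LabelParcellation",
    labels = array(as.integer(truthLab), dims),
    labelNames = config@labelNames, seedROI = mask, affine = roi@affine,
    metadata = list(source = "synthetic ground truth"))

  K <- config@nTargets
  s2 <- log(1 + config@noiseCV^2)
  extentVox <- diff(range(which(apply(mask, axisIndex(config@gradientAxis),
                                      any))))

  bundles <- withSeed(config@rngSeed, {
    lapply(seq_len(config@nSubjects), function(s) {
      sid <- sprintf("S%03d", s)
      jitterMM <- if (config@jitterSDmm > 0)
        stats::rnorm(1, 0, config@jitterSDmm) else 0
      jitterNorm <- (jitterMM / config@voxelSizeMM) / extentVox
      G <- profileMatrix(pos + jitterNorm, config@gradientCenters,
                         config@gradientWidth, widthMult)
      dens <- lapply(seq_len(K), function(t) {
        v <- G[, t]
        if (config@noiseCV > 0)
          v <- v * stats::rlnorm(length(v), meanlog = -s2 / 2,
                                 sdlog = sqrt(s2))
        vol <- array(0, dims)
        vol[inROI] <- v
        methods::new("DensityMap", values = vol, seedROI = mask,
                     affine = roi@affine, targetLabel = config@labelNames[t],
                     subjectID = sid, normalized = FALSE)
      })
      names(dens) <- config@labelNames
      methods::new("SubjectBundle", subjectID = sid, seedROI = roi,
                   densities = dens, truth = truth)
    })
  })
  methods::new("Cohort", config = config, seedROI = roi, truth = truth,
               subjects = bundles)
}

#' Simulate paired left/right cohorts with a plantable asymmetry
#'
#' The two hemispheres are generated as independent cohorts sharing one
#' geometry; `leftWidthMult` widens (or narrows) the density profile of
#' selected targets in the left hemisphere only, which moves the
#' winner-takes-all boundaries and so changes parcel volumes -- a planted
#' left/right effect that survives mean-intensity normalization (a pure
#' amplitude offset would not, since normalization divides it out).
#'
#' @param config A [CohortConfig-class]; the right hemisphere uses it
#'   verbatim, the left uses a derived RNG seed.
#' @param leftWidthMult Per-target width multipliers for the left
#'   hemisphere (default: no asymmetry).
#' @return List with elements `left` and `right`, each a [Cohort-class].
#' @export
simulateBilateralCohort <- function(config, leftWidthMult = NULL) {
  right <- simulateCohort(config)
  cfgL <- config
  cfgL@rngSeed <- deriveSeed(config@rngSeed, 1L)
  left <- simulateCohort(cfgL, widthMult = leftWidthMult)
  list(left = left, right = right)
}

#' Synthetic stimulation-site table
#'
#' Places one named mm-space point at the noiseless center of gravity of
#' each ground-truth parcel, plus one probe point displaced from the first
#' parcel's COG by a stated offset. Empty truth parcels are omitted with a
#' warning. The analog of a literature-derived table of optimal stimulation
#' coordinates, with a provenance tag per row.
#'
#' @param cohort A [Cohort-class] or a ground-truth
#'   [LabelParcellation-class].
#' @param labels Which parcels to place sites at (default all).
#' @param offsetMM Length-3 displacement of the probe point in mm.
#' @return data.frame with columns name, x, y, z, source.
#' @export
makeSiteTable <- function(cohort, labels = NULL, offsetMM = c(3, 4, 0)) {
  truth <- if (methods::is(cohort, "Cohort")) truthParcellation(cohort)
           else cohort
  stopifnot(methods::is(truth, "LabelParcellation"))
  if (is.null(labels)) labels <- labelNames(truth)
  stopifnot(length(labels) >= 1)
  rows <- list()
  for (lab in labels) {
    m <- parcelMask(truth, lab)
    if (sum(maskArray(m)) == 0L) {
      warning(sprintf("truth parcel '%s' is empty; site omitted", lab))
      next
    }
    cog <- centerOfGravity(m)
    rows[[lab]] <- data.frame(name = paste0("site_", lab),
                              x = cog[1], y = cog[2], z = cog[3],
                              source = "synthetic:truth-cog")
  }
  if (!length(rows))
    stop("all requested truth parcels are empty; no sites to place")
  out <- do.call(rbind, rows)
  first <- out[1, ]
  probe <- data.frame(name = "site_offset_probe",
                      x = first$x + offsetMM[1], y = first$y + offsetMM[2],
                      z = first$z + offsetMM[3],
                      source = sprintf("synthetic:offset(%s)mm",
                                       paste(offsetMM, collapse = ",")))
  out <- rbind(out, probe)
  rownames(out) <- NULL
  out
}

#' Fraction of seed voxels on which a parcellation recovers the truth
#'
#' @param parcellation A [LabelParcellation-class].
#' @param truth The ground-truth [LabelParcellation-class] on the same grid.
#' @return Scalar in [0,1].
#' @export
labelRecovery <- function(parcellation, truth) {
  checkSameGrid(parcelLabels(parcellation), parcelLabels(truth),
                "parcellation and truth")
  roi <- seedMask(truth)
  mean(parcelLabels(parcellation)[roi] == parcelLabels(truth)[roi])
}
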