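## Core segmentation engine: mean-intensity normalization of density maps
## and winner-takes-all hard segmentation, single-stage or chained across
## the two-stage hypothesis-driven design (relay nuclei by cortical targets,
## then the pallidal segments by relay-cluster targets).

#' Normalize a density map by its mean in-ROI intensity
#'
#' Divides every in-ROI voxel by the mean intensity of the map, making
#' density values comparable across targets before winner-takes-all
#' segmentation. By default the mean is taken over strictly positive in-ROI
#' voxels, so maps with sparse coverage are not inflated by their many
#' zeros; `meanMode = "all"` averages over every ROI voxel instead (both
#' behaviours are exposed for regression comparison). Zeros stay zero.
#'
#' @param map A [DensityMap-class] with at least one positive in-ROI voxel.
#' @param meanMode "positive" (default) or "all".
#' @return A normalized [DensityMap-class]; the mean of its strictly
#'   positive values equals 1 under the default mode.
#' @examples
#' roi <- array(TRUE, c(2, 2, 1))
#' m <- methods::new("DensityMap",
#'   values = array(c(1, 2, 3, 6), c(2, 2, 1)), seedROI = roi,
#'   affine = diag(4), targetLabel = "limbic", subjectID = "S001",
#'   normalized = FALSE)
#' densityValues(normalizeDensity(m))  # 1/3, 2/3, 1, 2
#' @export
normalizeDensity <- function(map, meanMode = c("positive", "all")) {
  meanMode <- match.arg(meanMode)
  stopifnot(methods::is(map, "DensityMap"))
  roi <- seedMask(map)
  vals <- densityValues(map)
  inROI <- vals[roi]
  if (!any(inROI > 0))
    stop(sprintf(
      "normalization error: all-zero density map (subject %s, target %s)",
      subjectID(map), targetLabel(map)))
  mu <- if (meanMode == "positive") mean(inROI[inROI > 0]) else mean(inROI)
  out <- vals
  out[roi] <- inROI / mu
  methods::initialize(map, values = out, normalized = TRUE)
}

#' Winner-takes-all segmentation of normalized density maps
#'
#' Assigns each seed voxel with at least one strictly positive density the
#' label of the map with the largest value there. Ties are broken by the
#' lowest target index (the fixed anterior-to-posterior target ordering),
#' and voxels where every map is zero remain unlabeled (0): attribution
#' presumes evidence of connectivity. The resulting partition is exclusive.
#'
#' @param maps List of >= 2 [DensityMap-class] objects sharing one seed ROI
#'   and grid, expected to be normalized (see [normalizeDensity()]).
#' @param metadata Optional provenance list stored on the output.
#' @return A [LabelParcellation-class] with `labelNames` in map order.
#' @export
winnerTakesAll <- function(maps, metadata = list()) {
  if (!is.list(maps) || length(maps) < 2L)
    stop("configuration error: winner-takes-all needs at least 2 density maps")
  stopifnot(all(vapply(maps, methods::is, logical(1), "DensityMap")))
  ref <- maps[[1L]]
  roi <- seedMask(ref)
  for (m in maps[-1L]) {
    checkSameGrid(densityValues(m), densityValues(ref), "density maps")
    if (!identical(seedMask(m), roi))
      stop("shape error: density maps disagree on the seed ROI")
  }
  inROI <- which(roi)
  vm <- vapply(maps, function(m) densityValues(m)[inROI],
               numeric(length(inROI)))
  vm <- matrix(vm, nrow = length(inROI))
  win <- argmaxFirst(vm)
  win[vm[cbind(seq_len(nrow(vm)), win)] <= 0] <- 0L
  labs <- integer(length(roi))
  labs[inROI] <- win
  methods::new("LabelParcellation",
    labels = array(as.integer(labs), dim(roi)),
    labelNames = unname(vapply(maps, targetLabel, character(1))),
    seedROI = roi, affine = affineMM(ref), metadata = metadata)
}

#' Normalize then segment one subject's density maps
#'
#' Convenience wrapper chaining [normalizeDensity()] over all maps and
#' [winnerTakesAll()].
#'
#' @inheritParams winnerTakesAll
#' @param meanMode Passed to [normalizeDensity()].
#' @return A [LabelParcellation-class].
#' @export
parcellateSubject <- function(maps, meanMode = c("positive", "all"),
                              metadata = list()) {
  meanMode <- match.arg(meanMode)
  winnerTakesAll(lapply(maps, normalizeDensity, meanMode = meanMode),
                 metadata = metadata)
}

## Tracking parameters of the pallidal (stage-2) seeding, recorded as
## provenance only: tractography itself is upstream of this package.
stage2SeedingParameters <- function() {
  list(seeds_per_voxel = 1000L, step = "1.25 x voxel size",
       angle = "30 degrees x step / voxel size", cutoff = 0.025)
}

#' Two-stage hypothesis-driven parcellation
#'
#' Stage 1 parcellates each relay nucleus (striatum, subthalamic nucleus,
#' thalamus) by its cortical connectivity into functional groups; stage 2
#' parcellates each pallidal segment using, per pathway, density maps whose
#' targets are the stage-1 clusters. With four functional groups the full
#' design yields 12 pallidal cluster maps for GPi (3 pathways) and 8 for
#' GPe (2 pathways). Stage-1 provenance (the relay whose clusters seeded
#' each stage-2 target, and the stage-2 tracking parameters) is recorded in
#' each output's metadata.
#'
#' @param stage1 Named list: relay nucleus -> list of subjects, each a list
#'   of cortical-target [DensityMap-class] objects.
#' @param stage2 Named list: pallidal nucleus -> named list: pathway -> list
#'   of subjects, each a list of [DensityMap-class] objects whose targets
#'   are the functional groups.
#' @param requiredGroups Functional groups every stage-1 parcellation must
#'   provide and every stage-2 pathway must target.
#' @param pathwayRelay Named character mapping pathway name -> relay
#'   nucleus, used for provenance and for checking stage-1 coverage.
#' @param expectedPathways Named list: nucleus -> pathways that must be
#'   present; missing combinations raise a configuration error.
#' @param meanMode Passed to [normalizeDensity()].
#' @return Nested list: nucleus -> pathway -> list of per-subject
#'   [LabelParcellation-class] objects. The stage-1 parcellations are
#'   attached as attribute `"stage1"`.
#' @export
twoStageParcellate <- function(stage1, stage2,
    requiredGroups = c("limbic", "associative", "sensorimotor", "other"),
    pathwayRelay = c(striatopallidal = "striatum",
                     subthalamopallidal = "stn",
                     pallidothalamic = "thalamus"),
    expectedPathways = list(
      GPi = c("striatopallidal", "subthalamopallidal", "pallidothalamic"),
      GPe = c("striatopallidal", "subthalamopallidal")),
    meanMode = c("positive", "all")) {
  meanMode <- match.arg(meanMode)

  ## stage 1: relay nuclei by cortical connectivity
  stage1Parcels <- lapply(names(stage1), function(relay) {
    lapply(stage1[[relay]], function(subjMaps) {
      p <- parcellateSubject(subjMaps, meanMode = meanMode,
                             metadata = list(stage = 1L, nucleus = relay,
                                             targets = "cortical groups"))
      missing <- setdiff(requiredGroups, labelNames(p))
      if (length(missing))
        stop(sprintf(
          "configuration error: stage-1 parcellation of %s lacks group(s): %s",
          relay, paste(missing, collapse = ", ")))
      p
    })
  })
  names(stage1Parcels) <- names(stage1)

  ## completeness of stage-2 inputs
  missingCombos <- character()
  for (nuc in names(expectedPathways)) {
    have <- names(stage2[[nuc]])
    for (pw in setdiff(expectedPathways[[nuc]], have))
      missingCombos <- c(missingCombos, paste(nuc, pw, sep = "/"))
    for (pw in intersect(expectedPathways[[nuc]], have)) {
      relay <- unname(pathwayRelay[pw])
      if (!is.na(relay) && !relay %in% names(stage1))
        missingCombos <- c(missingCombos,
                           paste0(nuc, "/", pw, " (relay ", relay,
                                  " absent from stage 1)"))
    }
  }
  if (length(missingCombos))
    stop("configuration error: missing pathway inputs: ",
         paste(missingCombos, collapse = "; "))

  ## stage 2: pallidal segments by relay-cluster connectivity
  out <- lapply(names(expectedPathways), function(nuc) {
    res <- lapply(expectedPathways[[nuc]], function(pw) {
      relay <- unname(pathwayRelay[pw])
      lapply(stage2[[nuc]][[pw]], function(subjMaps) {
        labs <- vapply(subjMaps, targetLabel, character(1))
        missing <- setdiff(requiredGroups, labs)
        if (length(missing))
          stop(sprintf(
            "configuration error: %s/%s stage-2 maps lack target(s): %s",
            nuc, pw, paste(missing, collapse = ", ")))
        parcellateSubject(subjMaps, meanMode = meanMode,
          metadata = list(stage = 2L, nucleus = nuc, pathway = pw,
                          stage1_relay = relay,
                          stage1_targets = requiredGroups,
                          tracking = stage2SeedingParameters()))
      })
    })
    names(res) <- expectedPathways[[nuc]]
    res
  })
  names(out) <- names(expectedPathways)
  attr(out, "stage1") <- stage1Parcels
  out
}

#' Count the pallidal cluster maps a two-stage result provides
#'
#' One cluster map per (nucleus, pathway, label); in the full four-group
#' design this is 12 for GPi and 8 for GPe.
#'
#' @param result Output of [twoStageParcellate()].
#' @return Named integer vector, one count per nucleus.
#' @export
countClusterMaps <- function(result) {
  vapply(result, function(pathways) {
    sum(vapply(pathways, function(parcels)
      length(labelNames(parcels[[1L]])), integer(1)))
  }, integer(1))
}

#' Simulate the complete two-stage pallidal design
#'
#' Builds synthetic stage-1 inputs (three relay nuclei parcellated by four
#' cortical groups) and stage-2 inputs (GPi with striatopallidal,
#' subthalamopallidal and pallidothalamic pathways; GPe with the first two)
#' from independent cohorts sharing the geometry of `config`, with RNG
#' seeds derived from `config@rngSeed`.
#'
#' @param config A [CohortConfig-class] describing every cohort's geometry
#'   and noise model.
#' @param widthMult Optional per-target profile width multipliers applied
#'   to the stage-2 (pallidal) cohorts, e.g. to plant a hemispheric
#'   asymmetry; see [simulateCohort()].
#' @return List with `stage1`, `stage2` (as expected by
#'   [twoStageParcellate()]) and `truth` (nucleus -> ground-truth
#'   [LabelParcellation-class]).
#' @export
simulateTwoStagePallidal <- function(config, widthMult = NULL) {
  relays <- c("striatum", "stn", "thalamus")
  nuclei <- list(GPi = c("striatopallidal", "subthalamopallidal",
                         "pallidothalamic"),
                 GPe = c("striatopallidal", "subthalamopallidal"))
  off <- 0L
  nextCohort <- function(wm = NULL) {
    off <<- off + 1L
    cfg <- config
    cfg@rngSeed <- deriveSeed(config@rngSeed, 100L + off)
    simulateCohort(cfg, widthMult = wm)
  }
  stage1 <- lapply(relays, function(r)
    lapply(subjects(nextCohort()), subjectDensities))
  names(stage1) <- relays

  truth <- list()
  stage2 <- lapply(names(nuclei), function(nuc) {
    res <- lapply(nuclei[[nuc]], function(pw) {
      coh <- nextCohort(widthMult)
      if (is.null(truth[[nuc]])) truth[[nuc]] <<- truthParcellation(coh)
      lapply(subjects(coh), subjectDensities)
    })
    names(res) <- nuclei[[nuc]]
    res
  })
  names(stage2) <- names(nuclei)
  list(stage1 = stage1, stage2 = stage2, truth = truth)
}
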