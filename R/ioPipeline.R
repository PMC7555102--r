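## NIfTI-based I/O and end-to-end orchestration: write/read synthetic
## cohorts with a YAML manifest, validate manifests before compute, and run
## the full analysis (simulate -> two-stage parcellation -> MPMs ->
## similarity -> laterality -> proximity) writing standard-format outputs.

#' Write a 3D volume as NIfTI with an explicit affine
#'
#' @param values Numeric/integer/logical 3D array.
#' @param affine 4x4 voxel-to-world matrix (RAS mm).
#' @param file Output path (.nii or .nii.gz).
#' @return The file path, invisibly.
#' @export
writeVolumeNifti <- function(values, affine, file) {
  img <- RNifti::asNifti(array(as.numeric(values), dim(values)))
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI volume with its affine
#'
#' @param file NIfTI path.
#' @return List with `values` (3D array) and `affine` (4x4 matrix).
#' @export
readVolumeNifti <- function(file) {
  img <- RNifti::readNifti(file)
  list(values = array(as.numeric(img), dim(img)),
       affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Write a cohort to disk as NIfTI volumes plus a YAML manifest
#'
#' One file per subject x target density map, plus the shared seed ROI and
#' ground-truth label volume; `manifest.yaml` records the grid descriptor,
#' the generating configuration and every file path.
#'
#' @param cohort A [Cohort-class].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohortConfigOf(cohort)
  aff <- affineMM(cohort@seedROI)
  writeVolumeNifti(seedMask(cohort), aff, file.path(dir, "seed_roi.nii.gz"))
  writeVolumeNifti(parcelLabels(truthParcellation(cohort)), aff,
                   file.path(dir, "truth_labels.nii.gz"))
  subjectsYaml <- lapply(subjects(cohort), function(sb) {
    files <- lapply(subjectDensities(sb), function(dm) {
      f <- sprintf("%s_%s.nii.gz", subjectID(dm), targetLabel(dm))
      writeVolumeNifti(densityValues(dm), aff, file.path(dir, f))
      f
    })
    list(id = subjectID(sb), densities = files)
  })
  manifest <- list(
    template = list(dim = as.integer(cfg@gridShape),
                    voxel_size_mm = cfg@voxelSizeMM),
    labels = cfg@labelNames,
    seed_roi = "seed_roi.nii.gz",
    truth = "truth_labels.nii.gz",
    config = list(
      n_subjects = cfg@nSubjects, grid_shape = as.integer(cfg@gridShape),
      voxel_size_mm = cfg@voxelSizeMM, n_targets = cfg@nTargets,
      gradient_axis = cfg@gradientAxis,
      gradient_centers = cfg@gradientCenters,
      gradient_width = cfg@gradientWidth, noise_cv = cfg@noiseCV,
      jitter_sd_mm = cfg@jitterSDmm, roi_half_axes = cfg@roiHalfAxes,
      rng_seed = cfg@rngSeed),
    subjects = subjectsYaml)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Validate a cohort manifest before any computation
#'
#' Checks that every referenced file exists (missing files are fatal), that
#' all volumes share the manifest's grid descriptor, that every subject
#' provides a density map for every label, and that no density volume is
#' all-zero (which could not enter winner-takes-all).
#'
#' @param manifest Path to a manifest YAML or an already-parsed list.
#' @param baseDir Directory file paths are relative to (defaults to the
#'   manifest's directory).
#' @return data.frame report with columns level ("error"/"warning"), item,
#'   message; zero rows for a clean manifest.
#' @export
validateManifest <- function(manifest, baseDir = NULL) {
  if (is.character(manifest)) {
    if (is.null(baseDir)) baseDir <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  if (is.null(baseDir)) stop("baseDir required for parsed manifests")
  report <- list()
  note <- function(level, item, message)
    report[[length(report) + 1L]] <<- data.frame(level = level, item = item,
                                                 message = message)
  files <- c(manifest$seed_roi, manifest$truth,
             unlist(lapply(manifest$subjects, function(s)
               unlist(s$densities))))
  missing <- files[!file.exists(file.path(baseDir, files))]
  if (length(missing))
    stop("missing file(s): ", paste(missing, collapse = ", "))

  expectDim <- as.integer(manifest$template$dim)
  labels <- unlist(manifest$labels)
  for (f in files) {
    v <- readVolumeNifti(file.path(baseDir, f))
    if (!identical(dim(v$values), expectDim))
      note("error", f, sprintf("grid mismatch: %s vs template %s",
                               paste(dim(v$values), collapse = "x"),
                               paste(expectDim, collapse = "x")))
  }
  for (s in manifest$subjects) {
    have <- names(s$densities)
    for (lab in setdiff(labels, have))
      note("error", s$id, sprintf("missing density map for label '%s'", lab))
    for (lab in have) {
      v <- readVolumeNifti(file.path(baseDir, s$densities[[lab]]))
      if (all(v$values == 0))
        note("warning", paste(s$id, lab, sep = "/"),
             "all-zero density volume")
    }
  }
  if (!length(report))
    return(data.frame(level = character(), item = character(),
                      message = character()))
  do.call(rbind, report)
}

#' Read a cohort previously written by [writeCohort()]
#'
#' @param dir Directory containing `manifest.yaml`.
#' @return A [Cohort-class].
#' @export
readCohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  cf <- manifest$config
  cfg <- cohortConfig(
    nSubjects = cf$n_subjects, gridShape = unlist(cf$grid_shape),
    voxelSizeMM = cf$voxel_size_mm, nTargets = cf$n_targets,
    gradientAxis = cf$gradient_axis,
    gradientCenters = unlist(cf$gradient_centers),
    gradientWidth = cf$gradient_width, noiseCV = cf$noise_cv,
    jitterSDmm = cf$jitter_sd_mm, roiHalfAxes = unlist(cf$roi_half_axes),
    labelNames = unlist(manifest$labels), rngSeed = cf$rng_seed)
  roiV <- readVolumeNifti(file.path(dir, manifest$seed_roi))
  mask <- array(roiV$values != 0, dim(roiV$values))
  roi <- methods::new("SeedROI", mask = mask, affine = roiV$affine)
  truthV <- readVolumeNifti(file.path(dir, manifest$truth))
  truth <- methods::new("LabelParcellation",
    labels = array(as.integer(round(truthV$values)), dim(mask)),
    labelNames = cfg@labelNames, seedROI = mask, affine = roiV$affine,
    metadata = list(source = "read from disk"))
  bundles <- lapply(manifest$subjects, function(s) {
    dens <- lapply(names(s$densities), function(lab) {
      v <- readVolumeNifti(file.path(dir, s$densities[[lab]]))
      methods::new("DensityMap", values = v$values, seedROI = mask,
                   affine = v$affine, targetLabel = lab, subjectID = s$id,
                   normalized = FALSE)
    })
    names(dens) <- names(s$densities)
    methods::new("SubjectBundle", subjectID = s$id, seedROI = roi,
                 densities = dens, truth = truth)
  })
  methods::new("Cohort", config = cfg, seedROI = roi, truth = truth,
               subjects = bundles)
}

pipelineDefaults <- function() {
  list(mode = "simulate", cohort = list(), left_width_mult = NULL,
       threshold = 0.5, n_perm = 2000L, alpha = 0.05, seed = 42L,
       steps = c("parcellate", "mpm", "similarity", "laterality",
                 "proximity"),
       write_volumes = TRUE)
}

#' Run the end-to-end pallidal parcellation analysis
#'
#' Simulates bilateral two-stage cohorts (GPi against striatopallidal,
#' subthalamopallidal and pallidothalamic pathways; GPe against the first
#' two), parcellates every subject, and then executes the enabled stages:
#' maximum probability maps with volumes/COGs, cross-pathway Dice and
#' OBL/TAO reproducibility tables, SDI lateralization with the t-max
#' permutation test, and COG-to-site proximity against a synthetic site
#' table. All tables are written as CSV, group maps as NIfTI, and a
#' machine-readable JSON summary is produced. The run is fully determined
#' by the manifest seed.
#'
#' @param manifest Path to a YAML run manifest or a list; recognised
#'   fields: `mode` ("simulate"), `cohort` (arguments to [cohortConfig()]),
#'   `left_width_mult` (per-target width multipliers planting a left/right
#'   asymmetry), `threshold` (population threshold, default 0.5), `n_perm`,
#'   `alpha`, `seed`, `steps`, `write_volumes`.
#' @param outDir Output directory.
#' @return The run summary list, invisibly; also written as
#'   `summary.json`.
#' @export
runPipeline <- function(manifest = list(), outDir) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  cfg <- utils::modifyList(pipelineDefaults(), manifest)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (cfg$mode != "simulate")
    stop("compute failure: only mode 'simulate' is implemented; ",
         "ingest external data via readCohort() and the module functions")
  steps <- cfg$steps
  threshold <- cfg$threshold

  cohortArgs <- cfg$cohort
  cohortArgs$rngSeed <- cfg$seed
  baseConfig <- do.call(cohortConfig, cohortArgs)

  ## two-stage simulation + parcellation, one hemisphere at a time
  hemis <- list()
  for (h in c("right", "left")) {
    hcfg <- baseConfig
    if (h == "left") hcfg@rngSeed <- deriveSeed(baseConfig@rngSeed, 17L)
    wm <- if (h == "left") unlist(cfg$left_width_mult) else NULL
    sim <- simulateTwoStagePallidal(hcfg, widthMult = wm)
    parcels <- twoStageParcellate(sim$stage1, sim$stage2)
    hemis[[h]] <- list(sim = sim, parcels = parcels)
  }

  summary <- list(package = "pallidoparc",
                  version = as.character(utils::packageVersion("pallidoparc")),
                  seed = cfg$seed, n_subjects = baseConfig@nSubjects,
                  threshold = threshold, steps = steps)
  nuclei <- names(hemis$right$parcels)

  ## group maps are shared by the mpm, similarity and proximity stages
  for (h in names(hemis))
    for (nuc in nuclei)
      for (pw in names(hemis[[h]]$parcels[[nuc]]))
        hemis[[h]]$groupmaps[[nuc]][[pw]] <-
          buildGroupMaps(hemis[[h]]$parcels[[nuc]][[pw]], threshold)
  nMaps <- vapply(nuclei, function(nuc)
    sum(vapply(hemis$right$groupmaps[[nuc]], length, integer(1))),
    integer(1))
  summary$n_mpm_maps_per_hemisphere <- as.list(nMaps)

  if ("mpm" %in% steps) {
    mpmRows <- list()
    for (h in names(hemis)) {
      for (nuc in nuclei) {
        for (pw in names(hemis[[h]]$parcels[[nuc]])) {
          gm <- hemis[[h]]$groupmaps[[nuc]][[pw]]
          mpms <- lapply(gm, `[[`, "mpm")
          mpmRows[[paste(h, nuc, pw)]] <-
            mpmTable(mpms, nucleus = nuc, pathway = pw, hemisphere = h)
          if (isTRUE(cfg$write_volumes)) {
            for (lab in names(gm)) {
              writeVolumeNifti(fractionValues(gm[[lab]]$pmap),
                               affineMM(gm[[lab]]$pmap),
                               file.path(outDir, sprintf("pmap_%s_%s_%s_%s.nii.gz",
                                                         h, nuc, pw, lab)))
              writeVolumeNifti(maskArray(gm[[lab]]$mpm),
                               affineMM(gm[[lab]]$mpm),
                               file.path(outDir, sprintf("mpm_%s_%s_%s_%s.nii.gz",
                                                         h, nuc, pw, lab)))
            }
          }
        }
      }
    }
    tab <- do.call(rbind, mpmRows)
    utils::write.csv(tab, file.path(outDir, "mpm_table.csv"),
                     row.names = FALSE)
  }

  if ("similarity" %in% steps) {
    diceRows <- list(); reproRows <- list()
    for (h in names(hemis)) {
      for (nuc in nuclei) {
        gmByPathway <- lapply(hemis[[h]]$groupmaps[[nuc]], function(gm)
          lapply(gm, `[[`, "mpm"))
        diceRows[[paste(h, nuc)]] <-
          diceTable(gmByPathway, nucleus = nuc, hemisphere = h)
        for (pw in names(hemis[[h]]$parcels[[nuc]]))
          reproRows[[paste(h, nuc, pw)]] <-
            reproducibilityTable(hemis[[h]]$parcels[[nuc]][[pw]],
                                 nucleus = nuc, pathway = pw,
                                 hemisphere = h)
      }
    }
    utils::write.csv(do.call(rbind, diceRows),
                     file.path(outDir, "dice_table.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, reproRows),
                     file.path(outDir, "reproducibility_table.csv"),
                     row.names = FALSE)
  }

  if ("laterality" %in% steps) {
    latRows <- list(); liRows <- list()
    for (nuc in nuclei) {
      for (pw in names(hemis$right$parcels[[nuc]])) {
        L <- sdiMatrix(hemis$left$parcels[[nuc]][[pw]])
        R <- sdiMatrix(hemis$right$parcels[[nuc]][[pw]])
        perm <- pairedPermutationTmax(L, R, nPerm = cfg$n_perm,
                                      alpha = cfg$alpha,
                                      rngSeed = deriveSeed(cfg$seed, 29L))
        st <- sdiSummaryTable(L, R, perm)
        st$nucleus <- nuc; st$pathway <- pw
        latRows[[paste(nuc, pw)]] <- st
        li <- liSummary(L, R)$summary
        li$nucleus <- nuc; li$pathway <- pw
        liRows[[paste(nuc, pw)]] <- li
      }
    }
    utils::write.csv(do.call(rbind, latRows),
                     file.path(outDir, "sdi_laterality_table.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, liRows),
                     file.path(outDir, "li_summary.csv"), row.names = FALSE)
  }

  if ("proximity" %in% steps) {
    ## sensorimotor GPi maps of each pathway vs synthetic sites
    truthGPi <- hemis$right$sim$truth$GPi
    sites <- makeSiteTable(truthGPi)
    gmGPi <- hemis$right$groupmaps$GPi
    smLab <- if ("sensorimotor" %in% labelNames(truthGPi)) "sensorimotor"
             else labelNames(truthGPi)[1]
    cogs <- do.call(rbind, lapply(names(gmGPi), function(pw) {
      m <- gmGPi[[pw]][[smLab]]$mpm
      cog <- centerOfGravity(m)
      data.frame(name = pw, x = cog[1], y = cog[2], z = cog[3])
    }))
    masks <- lapply(names(gmGPi), function(pw) gmGPi[[pw]][[smLab]]$mpm)
    names(masks) <- names(gmGPi)
    prox <- proximityReport(cogs, sites, masks)
    utils::write.csv(data.frame(map = rownames(prox@distances),
                                prox@distances, check.names = FALSE),
                     file.path(outDir, "proximity_distances.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(distances = prox@distances,
                              membership = prox@membership,
                              nearest = as.list(prox@nearest)),
                         file.path(outDir, "proximity_report.json"),
                         matrix = "rowmajor", auto_unbox = TRUE,
                         digits = NA)
    summary$proximity_nearest <- as.list(prox@nearest)
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
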