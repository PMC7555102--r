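test_that("normalization divides by the mean of positive in-ROI intensities", {
  ## constant map: everything becomes 1
  cst <- toyDensity(array(7, c(2, 2, 1)))
  expect_equal(densityValues(normalizeDensity(cst)),
               array(1, c(2, 2, 1)))
  expect_true(isNormalized(normalizeDensity(cst)))

  ## positives {1,2,3,6}: mean 3, values divided through
  m <- toyDensity(array(c(1, 2, 3, 6), c(2, 2, 1)))
  expect_equal(densityValues(normalizeDensity(m)),
               array(c(1, 2, 3, 6) / 3, c(2, 2, 1)))
  nm <- normalizeDensity(m)
  v <- densityValues(nm)[seedMask(nm)]
  expect_equal(mean(v[v > 0]), 1)

  ## zeros excluded from the mean and left untouched
  mz <- toyDensity(array(c(2, 4, 0, 0), c(2, 2, 1)))
  expect_equal(densityValues(normalizeDensity(mz)),
               array(c(2 / 3, 4 / 3, 0, 0), c(2, 2, 1)))
  ## the alternative convention averages over all ROI voxels
  expect_equal(densityValues(normalizeDensity(mz, meanMode = "all")),
               array(c(2 / 1.5, 4 / 1.5, 0, 0), c(2, 2, 1)))
})

test_that("all-zero maps cannot be normalized and the error names the map", {
  z <- toyDensity(array(0, c(2, 2, 1)), target = "limbic",
                  subject = "S007")
  expect_error(normalizeDensity(z), "S007")
  expect_error(normalizeDensity(z), "limbic")
})

test_that("winner-takes-all assigns the argmax label, leaves all-zero voxels unlabeled, and breaks ties low", {
  roi <- array(TRUE, c(3, 1, 1))
  mk <- function(v, t) toyDensity(array(v, c(3, 1, 1)), roi, target = t)
  ## voxel 1: values (0.5, 2.0, 1.0) -> label 2; voxel 2 all zero -> 0;
  ## voxel 3: exact tie between targets 1 and 3 -> lowest index wins
  p <- winnerTakesAll(list(mk(c(0.5, 0, 1.0), "A"),
                           mk(c(2.0, 0, 0.2), "B"),
                           mk(c(1.0, 0, 1.0), "C")))
  expect_identical(parcelLabels(p)[, 1, 1], c(2L, 0L, 1L))
  expect_identical(labelNames(p), c("A", "B", "C"))
})

test_that("two-voxel toy parcellation matches the brute-force argmax scan", {
  roi <- array(TRUE, c(2, 1, 1))
  A <- toyDensity(array(c(3, 1), c(2, 1, 1)), roi, target = "A")
  B <- toyDensity(array(c(1, 3), c(2, 1, 1)), roi, target = "B")
  p <- winnerTakesAll(list(A, B))
  expect_identical(parcelLabels(p)[, 1, 1], c(1L, 2L))
  bf <- bfWinnerTakesAll(list(densityValues(A), densityValues(B)), roi)
  expect_identical(parcelLabels(p), bf)
})

test_that("winner-takes-all equals the per-voxel maximum oracle on random fixtures with ties and zeros", {
  set.seed(421)
  for (rep in 1:20) {
    dims <- c(sample(3:6, 1), sample(3:6, 1), sample(2:4, 1))
    roi <- randomMask(dims, 0.8)
    roi[1, 1, 1] <- TRUE
    K <- sample(2:4, 1)
    vals <- lapply(seq_len(K), function(t) {
      v <- array(stats::rexp(prod(dims)), dims)
      v[stats::runif(prod(dims)) < 0.3] <- 0  # sparse zeros
      v[!roi] <- 0
      v
    })
    ## force exact ties on a few voxels
    tie <- which(roi)[seq_len(min(3, sum(roi)))]
    for (t in seq_len(K)) vals[[t]][tie] <- 0.5
    maps <- lapply(seq_len(K), function(t)
      toyDensity(vals[[t]], roi, target = paste0("t", t)))
    expect_identical(parcelLabels(winnerTakesAll(maps)),
                     bfWinnerTakesAll(vals, roi))
  }
})

test_that("winner-takes-all validates its inputs", {
  roi <- array(TRUE, c(2, 2, 1))
  A <- toyDensity(array(1, c(2, 2, 1)), roi)
  expect_error(winnerTakesAll(list(A)), "configuration error")
  B <- toyDensity(array(1, c(2, 1, 2)))
  expect_error(winnerTakesAll(list(A, B)), "shape error")
  roi2 <- array(c(TRUE, FALSE, TRUE, TRUE), c(2, 2, 1))
  C <- toyDensity(array(c(1, 0, 1, 1), c(2, 2, 1)), roi2)
  expect_error(winnerTakesAll(list(A, C)), "seed ROI")
})

test_that("parcellation is invariant to rescaling any input map", {
  set.seed(7)
  dims <- c(5, 6, 4)
  roi <- randomMask(dims, 0.9)
  vals <- lapply(1:3, function(t) {
    v <- array(stats::rexp(prod(dims)), dims); v[!roi] <- 0; v
  })
  maps <- lapply(1:3, function(t)
    toyDensity(vals[[t]], roi, target = paste0("t", t)))
  base <- parcellateSubject(maps)
  scaled <- maps
  scaled[[2]] <- toyDensity(vals[[2]] * 37.5, roi, target = "t2")
  expect_identical(parcelLabels(parcellateSubject(scaled)),
                   parcelLabels(base))
})

test_that("parcel sizes sum to the voxels with any positive density", {
  set.seed(8)
  dims <- c(6, 6, 3)
  roi <- randomMask(dims, 0.7)
  vals <- lapply(1:3, function(t) {
    v <- array(stats::rexp(prod(dims)), dims)
    v[stats::runif(prod(dims)) < 0.5] <- 0
    v[!roi] <- 0
    v
  })
  maps <- lapply(1:3, function(t)
    toyDensity(vals[[t]], roi, target = paste0("t", t)))
  p <- winnerTakesAll(maps)
  anyPos <- Reduce(`|`, lapply(vals, function(v) v > 0)) & roi
  expect_identical(sum(parcelLabels(p) > 0), sum(anyPos))
  expect_lte(sum(parcelLabels(p) > 0), sum(roi))
})

test_that("the full two-stage design yields 12 GPi and 8 GPe cluster maps", {
  sim <- simulateTwoStagePallidal(tinyConfig(nSubjects = 3L))
  res <- twoStageParcellate(sim$stage1, sim$stage2)
  counts <- countClusterMaps(res)
  expect_identical(counts[["GPi"]], 12L)
  expect_identical(counts[["GPe"]], 8L)
  ## provenance records the stage-1 relay behind each pathway
  meta <- provenance(res$GPi$pallidothalamic[[1]])
  expect_identical(meta$stage1_relay, "thalamus")
  expect_identical(meta$tracking$seeds_per_voxel, 1000L)
})

test_that("a noiseless two-stage chain reproduces the generator truth", {
  cfg <- tinyConfig(nSubjects = 2L, noiseCV = 0, jitterSDmm = 0)
  sim <- simulateTwoStagePallidal(cfg)
  res <- twoStageParcellate(sim$stage1, sim$stage2)
  for (nuc in names(res))
    for (pw in names(res[[nuc]]))
      for (p in res[[nuc]][[pw]])
        expect_identical(parcelLabels(p),
                         parcelLabels(sim$truth[[nuc]]))
})

test_that("missing pathway inputs are reported as configuration errors", {
  sim <- simulateTwoStagePallidal(tinyConfig(nSubjects = 2L))
  broken <- sim$stage2
  broken$GPi$pallidothalamic <- NULL
  expect_error(twoStageParcellate(sim$stage1, broken),
               "GPi/pallidothalamic")
})
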