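test_that("Dice, Tanimoto and alpha match their defining counts on constructed masks", {
  ## |A| = 100, |B| = 60, |A^B| = 40
  A <- array(FALSE, c(10, 10, 2)); A[1:100] <- TRUE
  B <- array(FALSE, c(10, 10, 2)); B[61:120] <- TRUE
  expect_equal(diceCoefficient(A, B), 0.5)          # 80/160
  expect_equal(weightingAlpha(A, B), 2 / 160)       # 0.0125
  ## |A^B| = 40, |AuB| = 120
  expect_equal(tanimotoCoefficient(A, B), 40 / 120)
  ## identical and disjoint masks
  expect_equal(diceCoefficient(A, A), 1.0)
  expect_equal(tanimotoCoefficient(A, A), 1.0)
  C <- array(FALSE, c(10, 10, 2)); C[101:150] <- TRUE
  expect_equal(diceCoefficient(A, C), 0.0)
  ## single-voxel masks: alpha = 1
  a1 <- array(FALSE, c(2, 2, 1)); a1[1] <- TRUE
  expect_equal(weightingAlpha(a1, a1), 1.0)
})

test_that("degenerate and mismatched masks raise errors", {
  e <- array(FALSE, c(2, 2, 1))
  expect_error(diceCoefficient(e, e), "value error")
  expect_error(tanimotoCoefficient(e, e), "value error")
  expect_error(weightingAlpha(e, e), "value error")
  expect_error(diceCoefficient(array(TRUE, c(2, 2, 1)),
                               array(TRUE, c(2, 1, 2))), "shape error")
})

test_that("metrics agree with brute-force formulas and identities on random fixtures", {
  set.seed(99)
  for (rep in 1:25) {
    dims <- c(sample(4:7, 1), sample(4:7, 1), sample(2:4, 1))
    A <- randomMask(dims, stats::runif(1, 0.2, 0.7))
    B <- randomMask(dims, stats::runif(1, 0.2, 0.7))
    if (sum(A) + sum(B) == 0) A[1] <- TRUE
    d <- diceCoefficient(A, B)
    t <- if (sum(A | B) > 0) tanimotoCoefficient(A, B) else NA
    expect_equal(d, bfDice(A, B), tolerance = 1e-12)
    if (!is.na(t)) {
      expect_equal(t, bfTanimoto(A, B), tolerance = 1e-12)
      ## algebraic identity D = 2T/(1+T), hence D >= T
      expect_equal(d, 2 * t / (1 + t), tolerance = 1e-12)
      expect_gte(d, t)
    }
    expect_equal(weightingAlpha(A, B), bfAlpha(A, B), tolerance = 1e-12)
    ## symmetry
    expect_equal(d, diceCoefficient(B, A))
  }
})

test_that("OBL matches the pairwise enumeration oracle and its boundary cases", {
  ## identical masks across subjects
  m <- randomMask(c(5, 5, 2), 0.5); m[1] <- TRUE
  expect_equal(as.numeric(overlapByLabel(list(m, m, m))), 1.0)
  ## two disjoint subjects
  a <- array(FALSE, c(4, 4, 1)); a[1:4] <- TRUE
  b <- array(FALSE, c(4, 4, 1)); b[5:8] <- TRUE
  expect_equal(as.numeric(overlapByLabel(list(a, b))), 0.0)
  ## three constructed subjects against the literal formula
  set.seed(3)
  masks <- lapply(1:3, function(i) randomMask(c(5, 4, 3), 0.45))
  expect_equal(as.numeric(overlapByLabel(masks)), bfOBL(masks),
               tolerance = 1e-12)
  expect_error(overlapByLabel(list(a)), "configuration error")
})

test_that("empty-in-both pairs are skipped with a warning and reported", {
  e <- array(FALSE, c(3, 3, 1))
  m <- array(FALSE, c(3, 3, 1)); m[1:3] <- TRUE
  expect_warning(v <- overlapByLabel(list(m, e, e)), "skipped")
  expect_identical(attr(v, "nSkipped"), 1L)   # the (e,e) pair
  expect_identical(attr(v, "nPairs"), 2L)
  ## value equals the oracle on the nonempty pairs
  expect_equal(as.numeric(v), bfOBL(list(m, e, e)), tolerance = 1e-12)
})

test_that("duplicating the pair list leaves OBL unchanged", {
  set.seed(4)
  masks <- lapply(1:4, function(i) randomMask(c(4, 4, 2), 0.5))
  pairs <- utils::combn(4, 2)
  v1 <- overlapByLabel(masks, pairs = pairs)
  v2 <- overlapByLabel(masks, pairs = cbind(pairs, pairs))
  expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-12)
})

test_that("TAO matches the double-sum oracle and reduces to OBL for one label", {
  set.seed(5)
  subj <- lapply(1:3, function(s)
    toyParcellation(array(sample(0:2, 36, replace = TRUE), c(4, 3, 3)),
                    c("a", "b")))
  labArrays <- lapply(subj, parcelLabels)
  expect_equal(as.numeric(totalAccumulatedOverlap(subj)),
               bfTAO(labArrays, 2), tolerance = 1e-12)
  ## identical parcellations -> 1
  expect_equal(as.numeric(totalAccumulatedOverlap(list(subj[[1]],
                                                       subj[[1]]))), 1.0)
  ## single-label parcellation: TAO = OBL of that label
  one <- lapply(1:3, function(s)
    toyParcellation(array(sample(0:1, 36, replace = TRUE), c(4, 3, 3)),
                    "a"))
  masks <- lapply(one, function(p) parcelLabels(p) == 1L)
  expect_equal(as.numeric(totalAccumulatedOverlap(one)),
               as.numeric(overlapByLabel(masks)), tolerance = 1e-12)
})

test_that("reproducibility decreases with jitter on fixed-seed cohorts", {
  taos <- sapply(c(0, 0.5, 1.5), function(j) {
    coh <- simulateCohort(cohortConfig(nSubjects = 8L, jitterSDmm = j,
                                       noiseCV = 0, rngSeed = 31L))
    as.numeric(totalAccumulatedOverlap(cohortParcels(coh)))
  })
  expect_equal(taos[1], 1.0)  # no jitter, no noise: identical parcels
  expect_true(all(diff(taos) < 0))
})

test_that("the Dice table covers every pathway pair and label", {
  coh <- simulateCohort(tinyConfig())
  gmA <- lapply(buildGroupMaps(cohortParcels(coh)), `[[`, "mpm")
  coh2 <- simulateCohort(tinyConfig(rngSeed = 43L))
  gmB <- lapply(buildGroupMaps(cohortParcels(coh2)), `[[`, "mpm")
  tab <- diceTable(list(striatopallidal = gmA, subthalamopallidal = gmB),
                   nucleus = "GPi", hemisphere = "left")
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$dice >= 0 & tab$dice <= 1))
  expect_identical(unique(tab$pathway_a), "striatopallidal")
})
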