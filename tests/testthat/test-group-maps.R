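## Fixture: 100 subjects on a tiny grid where label "a" covers voxel
## (1,1,1) in all subjects, voxel (2,1,1) in exactly half, and voxel
## (3,1,1) in none.
hundredSubjects <- function() {
  lapply(1:100, function(s) {
    lab <- array(0L, c(3, 2, 1))
    lab[1, 1, 1] <- 1L
    if (s <= 50) lab[2, 1, 1] <- 1L
    toyParcellation(lab, c("a", "b"))
  })
}

test_that("probability maps count covering subjects exactly", {
  pm <- buildProbabilityMap(hundredSubjects(), "a")
  fr <- fractionValues(pm)
  expect_equal(fr[1, 1, 1], 1.0)
  expect_equal(fr[2, 1, 1], 0.5)
  expect_equal(fr[3, 1, 1], 0.0)
  expect_error(buildProbabilityMap(hundredSubjects(), "zz"), "key error")
  mixed <- c(hundredSubjects()[1],
             list(toyParcellation(array(0L, c(2, 2, 1)), c("a", "b"))))
  expect_error(buildProbabilityMap(mixed, "a"), "shape error")
})

test_that("the population threshold is inclusive at exactly half the sample", {
  pm <- buildProbabilityMap(hundredSubjects(), "a")
  mpm <- thresholdMPM(pm, 0.5)
  expect_true(maskArray(mpm)[1, 1, 1])
  expect_true(maskArray(mpm)[2, 1, 1])   # exactly 50/100 retained
  expect_false(maskArray(mpm)[3, 1, 1])
  ## 49/100 is excluded
  subj <- hundredSubjects()
  lab <- parcelLabels(subj[[50]]); lab[2, 1, 1] <- 0L
  subj[[50]] <- toyParcellation(lab, c("a", "b"))
  expect_false(maskArray(thresholdMPM(buildProbabilityMap(subj, "a"),
                                      0.5))[2, 1, 1])
  ## threshold 1 keeps unanimity voxels only
  m1 <- thresholdMPM(pm, 1.0)
  expect_true(m1@mask[1, 1, 1]); expect_false(m1@mask[2, 1, 1])
})

test_that("raising the threshold never adds voxels", {
  set.seed(11)
  subj <- lapply(1:9, function(s)
    toyParcellation(array(sample(0:2, 24, replace = TRUE), c(4, 3, 2)),
                    c("a", "b")))
  pm <- buildProbabilityMap(subj, "a")
  prev <- maskArray(thresholdMPM(pm, 0.1))
  for (th in c(0.25, 0.5, 0.75, 1.0)) {
    cur <- maskArray(thresholdMPM(pm, th))
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("mask volume uses the affine determinant", {
  m <- array(FALSE, c(4, 4, 4)); m[1:5 * 2] <- TRUE
  mask10 <- array(FALSE, c(4, 4, 4)); mask10[1:10] <- TRUE
  mpm <- methods::new("MPMask", mask = mask10, labelName = "a",
                      thresholdFraction = 0.5,
                      affine = isotropicAffine(c(4L, 4L, 4L), 1.25))
  expect_equal(maskVolume(mpm), 10 * 1.25^3)  # 19.531 mm^3
  empty <- methods::new("MPMask", mask = array(FALSE, c(4, 4, 4)),
                        labelName = "a", thresholdFraction = 0.5,
                        affine = diag(4))
  expect_equal(maskVolume(empty), 0)
  sing <- methods::new("MPMask", mask = mask10, labelName = "a",
                       thresholdFraction = 0.5,
                       affine = diag(c(1, 1, 0, 1)))
  expect_error(maskVolume(sing), "geometry error")
})

test_that("center of gravity is the affine image of the voxel centroid", {
  aff <- isotropicAffine(c(5L, 5L, 5L), 2)
  one <- array(FALSE, c(5, 5, 5)); one[2, 3, 4] <- TRUE
  m <- methods::new("MPMask", mask = one, labelName = "a",
                    thresholdFraction = 0.5, affine = aff)
  expect_equal(unname(centerOfGravity(m)),
               drop(voxelToWorldMM(aff, c(2, 3, 4))))
  ## two voxels symmetric about the grid center -> origin (centered affine)
  two <- array(FALSE, c(5, 5, 5)); two[1, 3, 3] <- TRUE; two[5, 3, 3] <- TRUE
  m2 <- methods::new("MPMask", mask = two, labelName = "a",
                     thresholdFraction = 0.5, affine = aff)
  expect_equal(unname(centerOfGravity(m2)), c(0, 0, 0))
  ## translating the affine translates the COG
  aff2 <- aff; aff2[1:3, 4] <- aff2[1:3, 4] + c(10, -5, 2.5)
  m3 <- methods::new("MPMask", mask = two, labelName = "a",
                     thresholdFraction = 0.5, affine = aff2)
  expect_equal(unname(centerOfGravity(m3)),
               unname(centerOfGravity(m2)) + c(10, -5, 2.5))
  ## empty mask has no COG
  e <- methods::new("MPMask", mask = array(FALSE, c(5, 5, 5)),
                    labelName = "a", thresholdFraction = 0.5, affine = aff)
  expect_error(centerOfGravity(e), "empty")
})

test_that("group MPMs of different labels may overlap even though subject parcels are exclusive", {
  ## subjects disagree on the voxel: half call it a, half call it b, and a
  ## 50% threshold keeps it in both MPMs
  subj <- lapply(1:10, function(s) {
    lab <- array(0L, c(2, 2, 1))
    lab[1, 1, 1] <- if (s <= 5) 1L else 2L
    lab[2, 1, 1] <- 1L
    toyParcellation(lab, c("a", "b"))
  })
  gm <- buildGroupMaps(subj, 0.5)
  expect_true(maskArray(gm$a$mpm)[1, 1, 1] && maskArray(gm$b$mpm)[1, 1, 1])
  ## each subject-level parcellation remains exclusive
  for (p in subj)
    expect_true(all(tabulate(parcelLabels(p)) <= prod(dim(parcelLabels(p)))))
})

test_that("on a noiseless cohort the 50% MPM of each label equals the truth parcel", {
  coh <- simulateCohort(tinyConfig(nSubjects = 4L, noiseCV = 0,
                                   jitterSDmm = 0))
  parcels <- cohortParcels(coh)
  gm <- buildGroupMaps(parcels, 0.5)
  truth <- truthParcellation(coh)
  for (lab in labelNames(coh))
    expect_identical(maskArray(gm[[lab]]$mpm),
                     maskArray(parcelMask(truth, lab)))
})
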