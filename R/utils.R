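## Internal geometry and RNG helpers shared across modules.

#' Build an isotropic RAS affine for a voxel grid
#'
#' Constructs a 4x4 voxel-to-world matrix with isotropic scaling and a
#' translation that places the geometric center of the grid at the world
#' origin (so template coordinates are symmetric about 0 along every axis).
#'
#' @param gridShape Integer vector of length 3, grid dimensions in voxels.
#' @param voxelSizeMM Positive scalar, voxel edge length in mm.
#' @return A 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @export
isotropicAffine <- function(gridShape, voxelSizeMM) {
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1), voxelSizeMM > 0)
  aff <- diag(c(rep(voxelSizeMM, 3L), 1))
  aff[1:3, 4] <- -voxelSizeMM * (gridShape - 1) / 2
  aff
}

#' Map voxel indices to world (mm) coordinates
#'
#' Voxel indices follow the R convention (1-based); the affine acts on
#' 0-based indices as in the NIfTI standard, so the conversion subtracts 1.
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param ijk Numeric matrix (n x 3) or vector of length 3 of 1-based voxel
#'   indices (may be fractional, e.g. a centroid).
#' @return Matrix (n x 3) of mm coordinates.
#' @export
voxelToWorldMM <- function(affine, ijk) {
  ijk <- rbind(ijk)
  h <- cbind(ijk - 1, 1)
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' Map world (mm) coordinates to continuous 1-based voxel indices
#' @param affine 4x4 voxel-to-world matrix (must be invertible).
#' @param xyz Numeric matrix (n x 3) or vector of length 3, mm coordinates.
#' @return Matrix (n x 3) of continuous 1-based voxel indices.
#' @export
worldToVoxelMM <- function(affine, xyz) {
  if (abs(det(affine)) < .Machine$double.eps)
    stop("geometry error: affine is singular and cannot be inverted")
  xyz <- rbind(xyz)
  h <- cbind(xyz, 1) %*% t(solve(affine))
  h[, 1:3, drop = FALSE] + 1
}

#' Volume of one voxel in cubic millimetres
#' @param affine 4x4 voxel-to-world matrix.
#' @return Scalar, |det| of the 3x3 linear part, in mm^3.
#' @export
voxelVolumeMM3 <- function(affine) {
  abs(det(affine[1:3, 1:3]))
}

## Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed; keeps results < 2^31.
deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}

## Index of a gradient axis letter in c("x","y","z").
axisIndex <- function(axis) {
  ix <- match(axis, c("x", "y", "z"))
  if (is.na(ix)) stop("configuration error: gradient_axis must be x, y or z")
  ix
}

## Coerce a mask-like input (logical/numeric array or MPMask) to logical.
as01mask <- function(x) {
  if (methods::is(x, "MPMask")) x <- maskArray(x)
  if (is.logical(x)) return(x)
  if (!all(x %in% c(0, 1)))
    stop("mask values must be binary (0/1)")
  array(x != 0, dim = dim(x))
}

## Check that two arrays live on the same grid.
checkSameGrid <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape error: %s are on different grids (%s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
  invisible(TRUE)
}
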