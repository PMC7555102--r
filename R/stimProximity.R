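## Spatial relations between thresholded connectivity maps and named
## stimulation coordinates: Euclidean distances to map centers of gravity,
## membership of sites within maps, and per-site nearest-map rankings.

#' Euclidean distance between two mm-space points
#'
#' @param p,q Numeric length-3 coordinates (mm), or single rows of a site
#'   table with columns x, y, z.
#' @return Distance in mm.
#' @examples
#' euclideanDistanceMM(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
euclideanDistanceMM <- function(p, q) {
  p <- asXYZ(p); q <- asXYZ(q)
  if (any(!is.finite(p)) || any(!is.finite(q)))
    stop("coordinates must be finite")
  sqrt(sum((p - q)^2))
}

asXYZ <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1L, all(c("x", "y", "z") %in% names(p)))
    p <- c(p$x, p$y, p$z)
  }
  as.numeric(p)[1:3]
}

#' Is a mm coordinate inside a binary map?
#'
#' The coordinate is mapped through the inverse affine and rounded to the
#' nearest voxel; the site is "inside" iff that voxel lies within the grid
#' and carries the mask. Coordinates falling outside the grid bounding box
#' return "outside" with a warning.
#'
#' @param site Length-3 mm coordinate or single site-table row.
#' @param mask An [MPMask-class].
#' @return "inside" or "outside".
#' @export
siteMembership <- function(site, mask) {
  stopifnot(methods::is(mask, "MPMask"))
  xyz <- asXYZ(site)
  ijk <- round(drop(worldToVoxelMM(affineMM(mask), xyz)))
  dims <- dim(maskArray(mask))
  if (any(ijk < 1) || any(ijk > dims)) {
    warning("site lies outside the grid bounding box")
    return("outside")
  }
  if (maskArray(mask)[ijk[1], ijk[2], ijk[3]]) "inside" else "outside"
}

#' Distance, membership and ranking report for sites versus maps
#'
#' Builds the full Euclidean distance matrix between map centers of gravity
#' and site coordinates, the site-in-map membership matrix (when masks are
#' supplied), and a per-site ranking of maps by COG distance with the
#' nearest map flagged.
#'
#' @param cogs data.frame with columns name, x, y, z: one row per map COG.
#' @param sites data.frame with columns name, x, y, z (and optionally
#'   source): one row per stimulation site.
#' @param masks Optional named list of [MPMask-class], names matching
#'   `cogs$name`, enabling the membership matrix.
#' @return A [ProximityReport-class].
#' @export
proximityReport <- function(cogs, sites, masks = NULL) {
  stopifnot(is.data.frame(cogs), nrow(cogs) >= 1L,
            is.data.frame(sites), nrow(sites) >= 1L)
  if (anyDuplicated(cogs$name) || anyDuplicated(sites$name))
    stop("configuration error: duplicate map or site names")
  D <- matrix(NA_real_, nrow(cogs), nrow(sites),
              dimnames = list(cogs$name, sites$name))
  for (i in seq_len(nrow(cogs)))
    for (j in seq_len(nrow(sites)))
      D[i, j] <- euclideanDistanceMM(cogs[i, ], sites[j, ])

  if (!is.null(masks)) {
    if (!all(cogs$name %in% names(masks)))
      stop("configuration error: masks must be named after the maps in cogs")
    M <- matrix(NA_character_, nrow(cogs), nrow(sites),
                dimnames = dimnames(D))
    for (i in seq_len(nrow(cogs)))
      for (j in seq_len(nrow(sites)))
        M[i, j] <- siteMembership(sites[j, ], masks[[cogs$name[i]]])
  } else {
    M <- matrix(character(0), 0L, 0L)
  }
  ranking <- lapply(seq_len(ncol(D)), function(j)
    rownames(D)[order(D[, j])])
  names(ranking) <- colnames(D)
  nearest <- vapply(ranking, `[`, character(1), 1L)
  methods::new("ProximityReport", distances = D, membership = M,
               ranking = ranking, nearest = nearest)
}
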