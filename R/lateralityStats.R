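## Volume-based laterality statistics: streamline density index (SDI),
## lateralization index (LI) with +-0.1 dominance cutoffs, and the paired
## sign-flip permutation test with t-max familywise correction.

#' Streamline density index
#'
#' Parcel volume as a percentage of the seed-ROI volume:
#' `SDI = 100 * v / V_ROI` (both in voxels).
#'
#' @param v Parcel voxel count (0 <= v <= VROI). Vectorized.
#' @param VROI Seed-ROI voxel count (> 0).
#' @return SDI in percent.
#' @examples
#' sdi(50, 200)  # 25
#' @export
sdi <- function(v, VROI) {
  if (any(VROI <= 0)) stop("value error: V_ROI must be positive")
  if (any(v < 0) || any(v > VROI))
    stop("invariant violation: need 0 <= v <= V_ROI")
  100 * v / VROI
}

#' Per-subject SDI matrix of a parcellation set
#'
#' @param parcellations Per-subject [LabelParcellation-class] list.
#' @return Matrix subjects x labels of SDI percentages; row names are
#'   subject metadata-free indices, column names the label names.
#' @export
sdiMatrix <- function(parcellations) {
  labs <- labelNames(parcellations[[1L]])
  out <- t(vapply(parcellations, function(p) {
    VROI <- sum(seedMask(p))
    counts <- tabulate(parcelLabels(p)[seedMask(p)], nbins = length(labs))
    sdi(counts, VROI)
  }, numeric(length(labs))))
  colnames(out) <- labs
  out
}

#' Long-format SDI table with provenance keys
#'
#' @param parcellations Per-subject [LabelParcellation-class] list.
#' @param nucleus,pathway,hemisphere Provenance keys recycled across rows.
#' @return data.frame with columns subject, nucleus, pathway, label,
#'   hemisphere, v, V_ROI, sdi.
#' @export
sdiTable <- function(parcellations, nucleus = NA_character_,
                     pathway = NA_character_, hemisphere = NA_character_) {
  labs <- labelNames(parcellations[[1L]])
  rows <- lapply(seq_along(parcellations), function(s) {
    p <- parcellations[[s]]
    VROI <- sum(seedMask(p))
    counts <- tabulate(parcelLabels(p)[seedMask(p)], nbins = length(labs))
    data.frame(subject = sprintf("S%03d", s), nucleus = nucleus,
               pathway = pathway, label = labs, hemisphere = hemisphere,
               v = counts, V_ROI = VROI, sdi = sdi(counts, VROI))
  })
  do.call(rbind, rows)
}

#' Lateralization index with dominance categories
#'
#' `LI = (Left - Right) / (Left + Right)`; LI > 0.1 is called
#' left-lateralized, LI < -0.1 right-lateralized, anything in between not
#' lateralized (strict inequalities at the cutoffs).
#'
#' @param left,right Nonnegative SDI values (vectorized; paired
#'   elementwise). Any pair with `left + right == 0` is an error.
#' @param cutoff Dominance cutoff (default 0.1).
#' @return data.frame with columns li and category (factor with levels
#'   left_lateralized, not_lateralized, right_lateralized).
#' @examples
#' lateralizationIndex(3, 1)   # li 0.5, left_lateralized
#' @export
lateralizationIndex <- function(left, right, cutoff = 0.1) {
  if (length(left) != length(right))
    stop("left and right must have equal length")
  tot <- left + right
  if (any(tot == 0))
    stop("value error: LI undefined when Left + Right = 0")
  li <- (left - right) / tot
  category <- factor(ifelse(li > cutoff, "left_lateralized",
                     ifelse(li < -cutoff, "right_lateralized",
                            "not_lateralized")),
                     levels = c("left_lateralized", "not_lateralized",
                                "right_lateralized"))
  data.frame(li = li, category = category)
}

#' Subject-level LI matrix for paired hemisphere SDI matrices
#'
#' @param left,right Subjects x variables SDI matrices (matching shapes).
#' @param cutoff Dominance cutoff.
#' @return List with `li` (subjects x variables matrix) and `summary`
#'   (data.frame: per variable, percent of subjects left-, right- and
#'   not-lateralized).
#' @export
liSummary <- function(left, right, cutoff = 0.1) {
  stopifnot(identical(dim(left), dim(right)))
  li <- matrix(NA_real_, nrow(left), ncol(left),
               dimnames = dimnames(left))
  for (j in seq_len(ncol(left)))
    li[, j] <- lateralizationIndex(left[, j], right[, j], cutoff)$li
  summ <- data.frame(
    variable = colnames(left),
    pct_left = 100 * colMeans(li > cutoff),
    pct_right = 100 * colMeans(li < -cutoff),
    pct_not = 100 * colMeans(li >= -cutoff & li <= cutoff))
  rownames(summ) <- NULL
  list(li = li, summary = summ)
}

## Sign-flip t statistics for a flip matrix F (nPerm x n) against
## difference matrix d (n x p). Uses the fact that sum(d^2) is invariant
## under sign flips, so only the flipped means need computing.
flipTs <- function(F, d) {
  n <- nrow(d)
  mu <- (F %*% d) / n
  ssq <- matrix(colSums(d^2), nrow(mu), ncol(mu), byrow = TRUE)
  v <- (ssq - n * mu^2) / (n - 1)
  t <- mu / sqrt(v / n)
  t[v <= 0 & abs(mu) < 1e-12] <- 0
  t
}

#' Paired sign-flip permutation test with t-max familywise correction
#'
#' Tests left-versus-right differences of SDI profiles. For each variable
#' the observed statistic is the paired t on `d = left - right`. The null
#' is built by randomly flipping the sign of each subject's whole
#' difference vector (the same flips apply to every variable within a
#' permutation, preserving cross-variable correlation); each permutation
#' contributes the maximum over variables of |t|, and the corrected
#' two-sided p-value of variable j is `(1 + #{t-max >= |t_obs_j|}) /
#' (nPerm + 1)` (the add-one Monte-Carlo estimator, which cannot return
#' zero). With `exact = TRUE` all 2^n sign patterns are enumerated and
#' plain proportions are reported.
#'
#' Variables whose differences have zero variance but nonzero mean have an
#' undefined t; they are reported as NA and excluded from the max statistic
#' with a warning. All-zero difference vectors yield t = 0 and p = 1.
#'
#' @param left,right Subjects x variables matrices of SDI (equal shapes,
#'   >= 3 subjects, no missing values).
#' @param nPerm Number of Monte-Carlo permutations (default 50000).
#' @param alpha Nominal familywise level (default 0.05).
#' @param rngSeed Integer seed for the sign flips.
#' @param exact Enumerate all 2^n sign patterns instead of sampling
#'   (requires <= 20 subjects).
#' @return A [PermutationResult-class].
#' @export
pairedPermutationTmax <- function(left, right, nPerm = 50000L,
                                  alpha = 0.05, rngSeed = 1L,
                                  exact = FALSE) {
  left <- as.matrix(left); right <- as.matrix(right)
  if (!identical(dim(left), dim(right)))
    stop("shape error: left and right matrices must have equal dimensions")
  if (nrow(left) < 3L)
    stop("configuration error: need at least 3 subjects")
  if (anyNA(left) || anyNA(right))
    stop("missing values are not supported")
  d <- left - right
  n <- nrow(d); p <- ncol(d)
  vars <- colnames(d)
  if (is.null(vars)) vars <- paste0("V", seq_len(p))

  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  tObs <- mu / (sdv / sqrt(n))
  degenerateZero <- sdv == 0 & abs(mu) < 1e-12
  excluded <- sdv == 0 & !degenerateZero
  tObs[degenerateZero] <- 0
  tObs[excluded] <- NA_real_
  if (any(excluded))
    warning(sprintf(
      "variable(s) %s have zero-variance differences with nonzero mean; t undefined, excluded from the max statistic",
      paste(vars[excluded], collapse = ", ")))
  keep <- which(!excluded)

  if (exact) {
    if (n > 20L)
      stop("exact enumeration limited to 20 subjects (2^n sign patterns)")
    F <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    nPermUsed <- nrow(F)
  } else {
    F <- withSeed(rngSeed, matrix(sample(c(-1, 1), nPerm * n, replace = TRUE),
                                  nrow = nPerm))
    nPermUsed <- as.integer(nPerm)
  }
  tPerm <- abs(flipTs(F, d[, keep, drop = FALSE]))
  tmax <- if (length(keep)) apply(tPerm, 1L, max) else numeric(nrow(F))

  tol <- 1e-8
  pCor <- rep(NA_real_, p); pUnc <- rep(NA_real_, p)
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    if (exact) {
      pCor[j] <- mean(tmax >= abs(tObs[j]) - tol)
      pUnc[j] <- mean(tPerm[, jj] >= abs(tObs[j]) - tol)
    } else {
      pCor[j] <- (1 + sum(tmax >= abs(tObs[j]) - tol)) / (nPermUsed + 1)
      pUnc[j] <- (1 + sum(tPerm[, jj] >= abs(tObs[j]) - tol)) / (nPermUsed + 1)
    }
  }
  methods::new("PermutationResult", variables = vars, tObs = tObs,
               pCorrected = pCor, pUncorrected = pUnc, excluded = excluded,
               nPerm = nPermUsed, exact = exact, alpha = alpha,
               rngSeed = as.integer(rngSeed))
}

#' Mean/SD SDI summary with significance flags
#'
#' Mirrors a per-hemisphere SDI summary table: mean and SD per variable for
#' each hemisphere, flagged where the t-max-corrected p-value falls below
#' the familywise level.
#'
#' @param left,right Subjects x variables SDI matrices.
#' @param perm A [PermutationResult-class] from [pairedPermutationTmax()]
#'   on the same matrices.
#' @return data.frame with columns variable, mean_left, sd_left,
#'   mean_right, sd_right, t, p_corrected, significant.
#' @export
sdiSummaryTable <- function(left, right, perm) {
  data.frame(
    variable = perm@variables,
    mean_left = colMeans(left), sd_left = apply(left, 2, stats::sd),
    mean_right = colMeans(right), sd_right = apply(right, 2, stats::sd),
    t = perm@tObs, p_corrected = perm@pCorrected,
    significant = !is.na(perm@pCorrected) & perm@pCorrected < perm@alpha,
    row.names = NULL)
}
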