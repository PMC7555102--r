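## Overlap statistics: Dice between pairs of binary maps, the Tanimoto
## coefficient, and the size-weighted groupwise reproducibility measures
## OBL (overlap by label) and TAO (total accumulated overlap). Dice is the
## tool for comparing group-level MPMs across pathways; OBL/TAO operate on
## subject-level parcels across all unordered subject pairs.

#' Dice coefficient between two binary maps
#'
#' `D = 2 |A intersect B| / (|A| + |B|)`.
#'
#' @param A,B Binary masks: [MPMask-class] objects or logical/0-1 arrays on
#'   one grid.
#' @return Scalar in [0,1].
#' @export
diceCoefficient <- function(A, B) {
  a <- as01mask(A); b <- as01mask(B)
  checkSameGrid(a, b, "masks")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0)
    stop("value error: Dice undefined for two empty masks")
  2 * sum(a & b) / (na + nb)
}

#' Tanimoto coefficient between two binary maps
#'
#' `T = N(A intersect B) / N(A union B)`, where N counts voxels.
#'
#' @inheritParams diceCoefficient
#' @return Scalar in [0,1].
#' @export
tanimotoCoefficient <- function(A, B) {
  a <- as01mask(A); b <- as01mask(B)
  checkSameGrid(a, b, "masks")
  nu <- sum(a | b)
  if (nu == 0)
    stop("value error: Tanimoto undefined for two empty masks")
  sum(a & b) / nu
}

#' Inverse-size weighting coefficient
#'
#' `alpha = 2 / (|A| + |B|)`: the inverse of the mean of the two mask
#' volumes, used to prevent large parcels from dominating the groupwise
#' overlap sums.
#'
#' @inheritParams diceCoefficient
#' @return Positive scalar.
#' @export
weightingAlpha <- function(A, B) {
  a <- as01mask(A); b <- as01mask(B)
  checkSameGrid(a, b, "masks")
  s <- sum(a) + sum(b)
  if (s == 0)
    stop("value error: weighting coefficient undefined for two empty masks")
  2 / s
}

## Weighted intersection/union sums over a pair list; shared by OBL/TAO.
## Returns c(num, den, skipped).
pairSums <- function(masks, pairs) {
  num <- 0; den <- 0; skipped <- 0L
  for (p in seq_len(ncol(pairs))) {
    a <- masks[[pairs[1L, p]]]
    b <- masks[[pairs[2L, p]]]
    s <- sum(a) + sum(b)
    if (s == 0) { skipped <- skipped + 1L; next }
    alpha <- 2 / s
    num <- num + alpha * sum(a & b)
    den <- den + alpha * sum(a | b)
  }
  c(num = num, den = den, skipped = skipped)
}

#' Overlap by label (OBL): groupwise reproducibility of one cluster
#'
#' Size-weighted Tanimoto overlap of one label's parcel across all
#' unordered subject pairs:
#' `OBL = sum_m alpha_i N(A_i ^ B_i) / sum_m alpha_i N(A_i v B_i)`,
#' with `alpha = 2/(|A|+|B|)` and m ranging over all C(S,2) pairwise
#' combinations of subjects. Pairs where both parcels are empty are skipped
#' with a warning (alpha is undefined there); the skip count is attached as
#' attribute `"nSkipped"`, and `"nPairs"` records the pairs used.
#'
#' @param masks List (length >= 2) of binary masks for one label, one per
#'   subject, on one grid.
#' @param pairs Optional 2 x m index matrix selecting subject pairs
#'   (defaults to all unordered combinations).
#' @return Scalar in [0,1] with attributes `nPairs` and `nSkipped`.
#' @export
overlapByLabel <- function(masks, pairs = NULL) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("configuration error: OBL needs at least 2 subjects")
  masks <- lapply(masks, as01mask)
  for (m in masks[-1L]) checkSameGrid(m, masks[[1L]], "subject masks")
  if (is.null(pairs)) pairs <- utils::combn(length(masks), 2L)
  s <- pairSums(masks, pairs)
  if (s[["skipped"]] > 0L)
    warning(sprintf("%d subject pair(s) with both parcels empty skipped",
                    s[["skipped"]]))
  if (s[["den"]] == 0)
    stop("value error: no nonempty subject pairs; OBL undefined")
  structure(s[["num"]] / s[["den"]],
            nPairs = as.integer(ncol(pairs) - s[["skipped"]]),
            nSkipped = as.integer(s[["skipped"]]))
}

#' Total accumulated overlap (TAO): parcellation-wise reproducibility
#'
#' Extends OBL's weighted sums over all n labels of a parcellation:
#' `TAO = sum_m sum_{i=1..n} alpha_i N(A_i ^ B_i) /
#'        sum_m sum_{i=1..n} alpha_i N(A_i v B_i)`.
#' With a single label TAO reduces to that label's OBL. Label-pairs empty
#' in both subjects are skipped as in [overlapByLabel()].
#'
#' @param parcellations List (length >= 2) of [LabelParcellation-class]
#'   sharing `labelNames`, one per subject.
#' @param pairs Optional 2 x m subject-pair index matrix.
#' @return Scalar in [0,1] with attributes `nPairs` (label-pair terms used)
#'   and `nSkipped`.
#' @export
totalAccumulatedOverlap <- function(parcellations, pairs = NULL) {
  if (!is.list(parcellations) || length(parcellations) < 2L)
    stop("configuration error: TAO needs at least 2 subjects")
  labs <- labelNames(parcellations[[1L]])
  for (p in parcellations[-1L])
    if (!identical(labelNames(p), labs))
      stop("configuration error: subjects disagree on label names")
  if (is.null(pairs)) pairs <- utils::combn(length(parcellations), 2L)
  num <- 0; den <- 0; skipped <- 0L; used <- 0L
  for (i in seq_along(labs)) {
    masks <- lapply(parcellations, function(p)
      parcelLabels(p) == i & seedMask(p))
    s <- pairSums(masks, pairs)
    num <- num + s[["num"]]; den <- den + s[["den"]]
    skipped <- skipped + s[["skipped"]]
    used <- used + ncol(pairs) - s[["skipped"]]
  }
  if (skipped > 0L)
    warning(sprintf("%d label-pair term(s) empty in both subjects skipped",
                    skipped))
  if (den == 0)
    stop("value error: no nonempty terms; TAO undefined")
  structure(num / den, nPairs = as.integer(used),
            nSkipped = as.integer(skipped))
}

#' Dice table between pathway pairs of thresholded MPMs
#'
#' Computes the Dice coefficient between functionally homologous MPMs of
#' every pair of pathways, one row per label, mirroring a cross-pathway
#' similarity table.
#'
#' @param mpmsByPathway Named list: pathway -> named list of
#'   [MPMask-class] per label.
#' @param nucleus,hemisphere Provenance keys recycled across rows.
#' @return data.frame with columns nucleus, hemisphere, label,
#'   pathway_a, pathway_b, dice.
#' @export
diceTable <- function(mpmsByPathway, nucleus = NA_character_,
                      hemisphere = NA_character_) {
  pws <- names(mpmsByPathway)
  if (length(pws) < 2L)
    stop("configuration error: need at least two pathways for Dice")
  labs <- names(mpmsByPathway[[1L]])
  combos <- utils::combn(pws, 2L)
  rows <- list()
  for (cc in seq_len(ncol(combos))) {
    pa <- combos[1L, cc]; pb <- combos[2L, cc]
    for (lab in labs) {
      rows[[length(rows) + 1L]] <- data.frame(
        nucleus = nucleus, hemisphere = hemisphere, label = lab,
        pathway_a = pa, pathway_b = pb,
        dice = diceCoefficient(mpmsByPathway[[pa]][[lab]],
                               mpmsByPathway[[pb]][[lab]]))
    }
  }
  do.call(rbind, rows)
}

#' OBL/TAO reproducibility table for one parcellation
#'
#' @param parcellations Per-subject [LabelParcellation-class] list.
#' @param nucleus,pathway,hemisphere Provenance keys.
#' @return data.frame with one OBL row per label and a final TAO row
#'   (column `metric` distinguishes them).
#' @export
reproducibilityTable <- function(parcellations, nucleus = NA_character_,
                                 pathway = NA_character_,
                                 hemisphere = NA_character_) {
  labs <- labelNames(parcellations[[1L]])
  rows <- lapply(seq_along(labs), function(i) {
    masks <- lapply(parcellations, function(p)
      parcelLabels(p) == i & seedMask(p))
    val <- withCallingHandlers(overlapByLabel(masks),
                               warning = function(w) invokeRestart("muffleWarning"))
    data.frame(nucleus = nucleus, pathway = pathway,
               hemisphere = hemisphere, metric = "obl", label = labs[i],
               value = as.numeric(val),
               n_pairs = attr(val, "nPairs"))
  })
  tao <- withCallingHandlers(totalAccumulatedOverlap(parcellations),
                             warning = function(w) invokeRestart("muffleWarning"))
  rows[[length(rows) + 1L]] <- data.frame(
    nucleus = nucleus, pathway = pathway, hemisphere = hemisphere,
    metric = "tao", label = "all", value = as.numeric(tao),
    n_pairs = attr(tao, "nPairs"))
  do.call(rbind, rows)
}
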