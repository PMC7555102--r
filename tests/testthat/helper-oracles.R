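## Independent brute-force oracles and small fixture builders. The oracles
## implement the defining formulas literally (loops, no shared code with
## the package) so that package results can be checked against them.

toyDensity <- function(values, roi = NULL, target = "t1", subject = "S001",
                       affine = diag(4)) {
  stopifnot(length(dim(values)) == 3L)
  if (is.null(roi)) roi <- array(TRUE, dim(values))
  methods::new("DensityMap", values = values, seedROI = roi,
               affine = affine, targetLabel = target, subjectID = subject,
               normalized = FALSE)
}

toyParcellation <- function(labels, labelNames, roi = NULL,
                            affine = diag(4)) {
  labels <- array(as.integer(labels), dim(labels))
  if (is.null(roi)) roi <- array(TRUE, dim(labels))
  methods::new("LabelParcellation", labels = labels,
               labelNames = labelNames, seedROI = roi, affine = affine,
               metadata = list())
}

randomMask <- function(dims = c(6, 6, 4), p = 0.4) {
  array(stats::runif(prod(dims)) < p, dims)
}

## Per-voxel argmax scan: the literal winner-takes-all definition.
bfWinnerTakesAll <- function(valueList, roi) {
  dims <- dim(valueList[[1]])
  out <- array(0L, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (!roi[i, j, k]) next
      vals <- vapply(valueList, function(v) v[i, j, k], numeric(1))
      if (all(vals <= 0)) next
      out[i, j, k] <- which(vals == max(vals))[1]
    }
  out
}

bfDice <- function(A, B) 2 * sum(A & B) / (sum(A) + sum(B))
bfTanimoto <- function(A, B) sum(A & B) / sum(A | B)
bfAlpha <- function(A, B) 2 / (sum(A) + sum(B))

## Literal pairwise-enumeration OBL over all unordered subject pairs.
bfOBL <- function(masks) {
  S <- length(masks)
  num <- 0; den <- 0
  for (a in seq_len(S - 1)) for (b in seq((a + 1), S)) {
    A <- masks[[a]]; B <- masks[[b]]
    if (sum(A) + sum(B) == 0) next
    al <- 2 / (sum(A) + sum(B))
    num <- num + al * sum(A & B)
    den <- den + al * sum(A | B)
  }
  num / den
}

## Literal double-sum TAO over subject pairs and labels.
bfTAO <- function(labelArrays, nLabels) {
  S <- length(labelArrays)
  num <- 0; den <- 0
  for (lab in seq_len(nLabels)) {
    for (a in seq_len(S - 1)) for (b in seq((a + 1), S)) {
      A <- labelArrays[[a]] == lab
      B <- labelArrays[[b]] == lab
      if (sum(A) + sum(B) == 0) next
      al <- 2 / (sum(A) + sum(B))
      num <- num + al * sum(A & B)
      den <- den + al * sum(A | B)
    }
  }
  num / den
}

## Exhaustive sign-flip distribution of the paired t (single variable).
bfExhaustiveP <- function(d) {
  n <- length(d)
  tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))
  tobs <- abs(tstat(d))
  pats <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tnull <- apply(pats, 1, function(s) abs(tstat(s * d)))
  mean(tnull >= tobs - 1e-8)
}

## Subject parcellations of a cohort (normalize + winner-takes-all).
cohortParcels <- function(cohort) {
  lapply(subjects(cohort), function(s)
    parcellateSubject(subjectDensities(s)))
}

tinyConfig <- function(...) {
  args <- utils::modifyList(
    list(nSubjects = 4L, gridShape = c(12L, 20L, 10L),
         roiHalfAxes = c(4, 8, 3.5)),
    list(...))
  do.call(cohortConfig, args)
}
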