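## Label-shuffling inference: two-group permutation test on null-deviation
## values, one-way and pairwise PERMANOVA, Mantel and partial Mantel tests.
## All tests enumerate every distinct label arrangement when that is no
## more work than the requested number of permutations (the p-value is then
## exact); otherwise they Monte-Carlo sample arrangements and use the
## add-one convention p = (k + 1) / (n + 1), which can never return 0.

.EPS <- 1e-12

#' Two-group label-shuffling permutation test of a mean difference
#'
#' Tests whether the means of `a` and `b` (e.g. aboveground vs belowground
#' null-deviation values within a chronosequence year) could differ by
#' chance, by shuffling the group labels over the pooled values and
#' counting arrangements whose absolute mean difference is at least the
#' observed one (two-sided).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param nPermutations Monte-Carlo permutations (default 9999); when the
#'   number of distinct label arrangements `choose(length(a) + length(b),
#'   length(a))` is no larger, every arrangement is enumerated and the
#'   p-value is exact.
#' @param seed integer seed for the Monte-Carlo case; NULL uses the current
#'   stream.
#' @return A [PermutationTestResult-class].
#' @examples
#' twoGroupPermutationTest(c(10, 11), c(1, 2))  # exhaustive: p = 2/6
#' @export
twoGroupPermutationTest <- function(a, b, nPermutations = 9999L, seed = NULL) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  obs <- mean(a) - mean(b)
  vals <- c(a, b)
  na <- length(a)
  n <- length(vals)
  if (all(vals == vals[1])) {
    warning("all values identical across both groups; p = 1")
    return(new("PermutationTestResult", observedDiff = 0, pValue = 1,
               nPermutations = 0L, twoSided = TRUE, exhaustive = TRUE))
  }
  nArr <- choose(n, na)
  exhaustive <- nArr <= nPermutations
  if (exhaustive) {
    sets <- combn(n, na)
    diffs <- apply(sets, 2L, function(idx) mean(vals[idx]) - mean(vals[-idx]))
    p <- mean(abs(diffs) >= abs(obs) - .EPS)
    nPerm <- as.integer(nArr)
  } else {
    k <- .withSeed(seed, {
      sum(vapply(seq_len(nPermutations), function(i) {
        idx <- sample.int(n, na)
        abs(mean(vals[idx]) - mean(vals[-idx])) >= abs(obs) - .EPS
      }, logical(1)))
    })
    p <- (k + 1) / (nPermutations + 1)
    nPerm <- as.integer(nPermutations)
  }
  new("PermutationTestResult", observedDiff = obs, pValue = p,
      nPermutations = nPerm, twoSided = TRUE, exhaustive = exhaustive)
}

#' Mean squares and pseudo-F from a PERMANOVA sum-of-squares decomposition
#'
#' @param ssAmong,ssResid among-group and residual sums of squares (>= 0).
#' @param dfAmong,dfResid their degrees of freedom (> 0).
#' @return list with `msAmong`, `msResid`, `pseudoF` where MS = SS / df and
#'   pseudo-F = msAmong / msResid.
#' @examples
#' computePseudoF(1.54, 4, 6.29, 35)  # MS_among 0.385, F ~ 2.14
#' @export
computePseudoF <- function(ssAmong, dfAmong, ssResid, dfResid) {
  if (dfAmong <= 0 || dfResid <= 0) stop("degrees of freedom must be > 0")
  if (ssAmong < 0 || ssResid < 0) stop("sums of squares must be >= 0")
  msAmong <- ssAmong / dfAmong
  msResid <- ssResid / dfResid
  if (msResid == 0) stop("residual mean square is 0; pseudo-F undefined")
  list(msAmong = msAmong, msResid = msResid, pseudoF = msAmong / msResid)
}

# within-group SS of a squared-distance matrix for integer group codes
.ssWithin <- function(d2, codes, nLevels) {
  ssw <- 0
  for (g in seq_len(nLevels)) {
    idx <- which(codes == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssw
}

#' One-way PERMANOVA on a distance matrix
#'
#' Decomposes the total sum of squared dissimilarities,
#' SS_total = (1/N) * sum over pairs of d_ij^2, into a within-group part
#' (per-group pair sums scaled by group size) and an among-group remainder,
#' forms pseudo-F = MS_among / MS_residual, and obtains the p-value by
#' permuting group labels and counting permuted pseudo-F values at least as
#' large as the observed one. On Euclidean distances of univariate data
#' this reproduces the classical one-way ANOVA F exactly.
#'
#' @param dm a [DistanceMatrix-class].
#' @param groups group label per sample (vector or the name of a metadata
#'   column is not accepted here; pass labels aligned with
#'   `sampleNames(dm)`); >= 2 groups, each with >= 2 samples.
#' @param nPermutations Monte-Carlo permutations (default 9999); all
#'   distinct label arrangements are enumerated instead when there are no
#'   more of them than `nPermutations`.
#' @param seed integer seed for the Monte-Carlo case.
#' @return A [PermanovaResult-class].
#' @seealso [pairwisePermanova()], [computePseudoF()]
#' @export
permanovaOneWay <- function(dm, groups, nPermutations = 9999L, seed = NULL) {
  d <- as.matrix(dm)
  n <- nrow(d)
  groups <- .asGroups(groups, n)
  if (nlevels(groups) < 2) stop("at least 2 groups required")
  d2 <- d^2
  sizes <- as.integer(table(groups))
  nLev <- nlevels(groups)
  ssTotal <- sum(d2) / (2 * n)
  codes <- as.integer(groups)
  ssWithin <- .ssWithin(d2, codes, nLev)
  ssAmong <- ssTotal - ssWithin
  dfAmong <- nLev - 1L
  dfResid <- n - nLev
  f <- computePseudoF(ssAmong, dfAmong, ssWithin, dfResid)
  statF <- function(cd) {
    ssw <- .ssWithin(d2, cd, nLev)
    ((ssTotal - ssw) / dfAmong) / (ssw / dfResid)
  }
  nArr <- .nArrangements(sizes)
  exhaustive <- nArr <= nPermutations
  if (exhaustive) {
    asg <- .enumerateAssignments(sizes)
    fs <- apply(asg, 1L, statF)
    p <- mean(fs >= f$pseudoF - .EPS)
    nPerm <- as.integer(round(nArr))
  } else {
    k <- .withSeed(seed, {
      sum(vapply(seq_len(nPermutations), function(i) {
        statF(sample(codes)) >= f$pseudoF - .EPS
      }, logical(1)))
    })
    p <- (k + 1) / (nPermutations + 1)
    nPerm <- as.integer(nPermutations)
  }
  tab <- data.frame(
    Source = c("Among", "Residual", "Total"),
    df = c(dfAmong, dfResid, n - 1L),
    SS = c(ssAmong, ssWithin, ssTotal),
    MS = c(f$msAmong, f$msResid, NA_real_),
    stringsAsFactors = FALSE)
  new("PermanovaResult", table = tab, pseudoF = f$pseudoF, pValue = p,
      nPermutations = nPerm, exhaustive = exhaustive)
}

#' Pairwise PERMANOVA over all group pairs
#'
#' One-way PERMANOVA restricted to each pair of groups (the follow-up the
#' standard workflow runs only when the one-way test is significant).
#' No multiplicity correction is applied by default; `correction = "holm"`
#' adds Holm-adjusted p-values.
#'
#' @inheritParams permanovaOneWay
#' @param correction "none" (default) or "holm".
#' @return data.frame with one row per pair: groupA, groupB, dfAmong,
#'   dfResid, ssAmong, ssResid, pseudoF, pValue, and pAdjusted when a
#'   correction is requested.
#' @export
pairwisePermanova <- function(dm, groups, nPermutations = 9999L, seed = NULL,
                              correction = c("none", "holm")) {
  correction <- match.arg(correction)
  groups <- .asGroups(groups, nrow(as.matrix(dm)))
  levs <- levels(groups)
  prs <- combn(levs, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    keep <- which(groups %in% prs[, j])
    res <- permanovaOneWay(subsetSamples(dm, keep), droplevels(groups[keep]),
                           nPermutations = nPermutations,
                           seed = if (is.null(seed)) NULL else seed + j)
    data.frame(groupA = prs[1L, j], groupB = prs[2L, j],
               dfAmong = res@table$df[1], dfResid = res@table$df[2],
               ssAmong = res@table$SS[1], ssResid = res@table$SS[2],
               pseudoF = res@pseudoF, pValue = res@pValue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (correction == "holm")
    out$pAdjusted <- stats::p.adjust(out$pValue, method = "holm")
  out
}

.alignTo <- function(dm, ref) {
  if (identical(sampleNames(dm), sampleNames(ref))) return(as.matrix(dm))
  if (!setequal(sampleNames(dm), sampleNames(ref)))
    stop("distance matrices must cover the same sample set")
  as.matrix(dm)[sampleNames(ref), sampleNames(ref)]
}

# residuals of y on z (both lower-triangle vectors) from a simple linear fit
.residualOn <- function(y, z) {
  b <- stats::cov(y, z) / stats::var(z)
  y - mean(y) - b * (z - mean(z))
}

.mantelEngine <- function(rx, yMat, stat, n, nPermutations, seed) {
  # stat(yTriangle) -> correlation-type statistic; permutes rows+columns of
  # yMat jointly; exhaustive over all n! relabelings when feasible
  ut <- lower.tri(yMat)
  robs <- stat(yMat[ut])
  exhaustive <- factorial(n) <= nPermutations
  if (exhaustive) {
    perms <- .allPermutations(n)
    rs <- vapply(perms, function(p) stat(yMat[p, p][ut]), numeric(1))
    p <- mean(rs >= robs - .EPS)
    nPerm <- as.integer(factorial(n))
  } else {
    k <- .withSeed(seed, {
      sum(vapply(seq_len(nPermutations), function(i) {
        pp <- sample.int(n)
        stat(yMat[pp, pp][ut]) >= robs - .EPS
      }, logical(1)))
    })
    p <- (k + 1) / (nPermutations + 1)
    nPerm <- as.integer(nPermutations)
  }
  list(r = robs, p = p, nPerm = nPerm, exhaustive = exhaustive)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the vectorized strict lower triangles of `dx`
#' (e.g. community Sorensen distances) and `dy` (e.g. environmental
#' Euclidean distances), with a one-sided upper-tail p-value obtained by
#' jointly permuting the rows and columns of `dy`.
#'
#' @param dx,dy [DistanceMatrix-class] objects over the same samples
#'   (`dy` is reordered to `dx` when needed); at least 4 samples.
#' @param nPermutations Monte-Carlo permutations (default 9999); all `N!`
#'   relabelings are enumerated instead when feasible.
#' @param seed integer seed for the Monte-Carlo case.
#' @return A [MantelResult-class].
#' @seealso [partialMantelTest()]
#' @export
mantelTest <- function(dx, dy, nPermutations = 9999L, seed = NULL) {
  x <- as.matrix(dx)
  n <- nrow(x)
  if (n < 4) stop("Mantel test needs at least 4 samples")
  y <- .alignTo(dy, dx)
  rx <- .lowerTri(x)
  if (var(rx) == 0 || var(.lowerTri(y)) == 0)
    stop("zero variance in a distance-matrix triangle; r undefined")
  res <- .mantelEngine(rx, y, stat = function(yt) stats::cor(rx, yt),
                       n = n, nPermutations = nPermutations, seed = seed)
  new("MantelResult", r = res$r, pValue = res$p, nPermutations = res$nPerm,
      partial = FALSE, controlled = "", exhaustive = res$exhaustive)
}

#' Partial Mantel test controlling a third distance matrix
#'
#' Correlates the residuals of `dx` and `dy` after simple linear fits of
#' each on `dz` (method of residuals). The permutation scheme permutes the
#' residual matrix of `dy` given `dz` jointly over rows and columns,
#' keeping the `dx` residuals fixed (one-sided upper tail).
#'
#' @param dx,dy,dz aligned [DistanceMatrix-class] objects; `dz` is the
#'   matrix controlled for.
#' @inheritParams mantelTest
#' @param controlled label recorded for the controlled matrix.
#' @return A [MantelResult-class] with `partial = TRUE`.
#' @export
partialMantelTest <- function(dx, dy, dz, nPermutations = 9999L, seed = NULL,
                              controlled = "dz") {
  x <- as.matrix(dx)
  n <- nrow(x)
  if (n < 4) stop("partial Mantel test needs at least 4 samples")
  y <- .alignTo(dy, dx)
  z <- .alignTo(dz, dx)
  ut <- lower.tri(x)
  xt <- x[ut]; yt <- y[ut]; zt <- z[ut]
  if (var(xt) == 0 || var(yt) == 0 || var(zt) == 0)
    stop("zero variance in a distance-matrix triangle; partial r undefined")
  rx <- .residualOn(xt, zt)
  if (var(rx) == 0) stop("dx is fully explained by dz; partial r undefined")
  # residual matrix of dy | dz, permuted as a distance matrix
  ryMat <- matrix(0, n, n, dimnames = dimnames(y))
  ryMat[ut] <- .residualOn(yt, zt)
  ryMat <- ryMat + t(ryMat)
  stat <- function(ryTri) {
    if (var(ryTri) == 0) return(0)
    stats::cor(rx, ryTri)
  }
  res <- .mantelEngine(rx, ryMat, stat = stat, n = n,
                       nPermutations = nPermutations, seed = seed)
  new("MantelResult", r = res$r, pValue = res$p, nPermutations = res$nPerm,
      partial = TRUE, controlled = controlled, exhaustive = res$exhaustive)
}
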