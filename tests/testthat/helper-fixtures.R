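# Fixture builders and independent oracles shared across test files.
# Oracles deliberately use their own arithmetic (or vegan), never the
# package internals they check.

# random community matrix with no empty samples or species
makeRandomCommunity <- function(nSamples, nSpecies, seed, lambda = 2,
                                metadata = NULL) {
  set.seed(seed)
  m <- matrix(rpois(nSamples * nSpecies, lambda), nSamples, nSpecies,
              dimnames = list(sprintf("s%02d", seq_len(nSamples)),
                              sprintf("sp%02d", seq_len(nSpecies))))
  for (i in which(rowSums(m) == 0)) m[i, sample.int(nSpecies, 1)] <- 1
  for (j in which(colSums(m) == 0)) m[sample.int(nSamples, 1), j] <- 1
  CommunityMatrix(m, metadata %||%
                    data.frame(row.names = rownames(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# presence-absence community from explicit member lists
makePresenceCommunity <- function(members, nSpecies) {
  m <- matrix(0, length(members), nSpecies,
              dimnames = list(sprintf("s%d", seq_along(members)),
                              sprintf("sp%d", seq_len(nSpecies))))
  for (i in seq_along(members)) m[i, members[[i]]] <- 1
  CommunityMatrix(m)
}

# Sorensen dissimilarity from the a/b/c contingency, written out directly
oracleSorensen <- function(x, y) {
  a <- sum(x > 0 & y > 0)
  b <- sum(x > 0 & y == 0)
  c <- sum(x == 0 & y > 0)
  (b + c) / (2 * a + b + c)
}

# mean pairwise Sorensen over rows of a presence matrix, via oracleSorensen
oracleMeanBeta <- function(pa) {
  n <- nrow(pa)
  prs <- utils::combn(n, 2)
  mean(vapply(seq_len(ncol(prs)), function(j)
    oracleSorensen(pa[prs[1, j], ], pa[prs[2, j], ]), numeric(1)))
}

# exhaustive null beta for equiprobable draws: all combinations of
# richness-k subsets per sample, every assemblage tuple equally likely
oracleExhaustiveNullBeta <- function(richness, poolSize) {
  subsets <- lapply(richness, function(k) {
    cs <- utils::combn(poolSize, k)
    lapply(seq_len(ncol(cs)), function(j) {
      v <- numeric(poolSize); v[cs[, j]] <- 1; v
    })
  })
  grids <- do.call(expand.grid, lapply(subsets, seq_along))
  mean(vapply(seq_len(nrow(grids)), function(i) {
    pa <- do.call(rbind, lapply(seq_along(subsets), function(s)
      subsets[[s]][[grids[i, s]]]))
    oracleMeanBeta(pa)
  }, numeric(1)))
}

# all permutations of 1..n (iterative construction, independent of the
# package's recursive generator)
oraclePermutations <- function(n) {
  perms <- list(1L)
  for (k in 2:n) {
    out <- list()
    for (p in perms)
      for (pos in 0:(k - 1))
        out[[length(out) + 1L]] <- append(p, k, after = pos)
    perms <- out
  }
  perms
}

# exhaustive two-sided two-group permutation p, straight from its definition
oracleTwoGroupP <- function(a, b) {
  vals <- c(a, b)
  na <- length(a)
  sets <- utils::combn(length(vals), na)
  obs <- abs(mean(a) - mean(b))
  diffs <- apply(sets, 2, function(idx)
    abs(mean(vals[idx]) - mean(vals[-idx])))
  mean(diffs >= obs - 1e-12)
}

# PERMANOVA pseudo-F through vegan::adonis2 (independent implementation)
oracleAdonisF <- function(dmat, groups) {
  g <- factor(groups)
  fit <- vegan::adonis2(stats::as.dist(dmat) ~ g, permutations = 2)
  fit$F[1]
}

# exhaustive PERMANOVA p for two groups, counting F over all label splits
oraclePermanova2P <- function(dmat, groups) {
  g <- factor(groups)
  lev <- levels(g)
  na <- sum(g == lev[1])
  n <- length(g)
  fObs <- oracleAdonisF(dmat, g)
  sets <- utils::combn(n, na)
  fs <- apply(sets, 2, function(idx) {
    gg <- rep(lev[2], n)
    gg[idx] <- lev[1]
    oracleAdonisF(dmat, gg)
  })
  mean(fs >= fObs - 1e-9)
}
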