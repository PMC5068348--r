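# Label-shuffling inference: two-group test, PERMANOVA, Mantel.

test_that("two-group permutation test enumerates small instances exactly", {
  res <- twoGroupPermutationTest(c(10, 11), c(1, 2))
  expect_true(res@exhaustive)
  expect_equal(res@nPermutations, 6L)
  # both extreme splits counted under the >= convention
  expect_equal(res@pValue, 2 / 6, tolerance = 1e-12)
  expect_equal(res@observedDiff, 9)

  # zero observed difference: every arrangement is at least as extreme
  flat <- twoGroupPermutationTest(c(1, 2), c(1, 2))
  expect_equal(flat@pValue, 1)

  # degenerate all-identical input warns and returns p = 1
  expect_warning(deg <- twoGroupPermutationTest(c(3, 3), c(3, 3)),
                 "identical")
  expect_equal(deg@pValue, 1)
  expect_error(twoGroupPermutationTest(1, c(1, 2)), "at least 2")
})

test_that("exhaustive p agrees with the enumeration oracle; MC converges", {
  set.seed(16)
  for (i in 1:5) {
    a <- rnorm(sample(3:5, 1))
    b <- rnorm(sample(3:5, 1), mean = 0.5)
    res <- twoGroupPermutationTest(a, b, nPermutations = 100000)
    expect_true(res@exhaustive)
    expect_equal(res@pValue, oracleTwoGroupP(a, b), tolerance = 1e-12)
  }
  # Monte-Carlo estimate within 3 binomial SEs of the exact value
  # (5 vs 5: 252 arrangements, so 200 requested permutations stay MC)
  for (i in 1:5) {
    a <- rnorm(5)
    b <- rnorm(5, mean = 0.5)
    exact <- twoGroupPermutationTest(a, b, nPermutations = 100000)
    mc <- twoGroupPermutationTest(a, b, nPermutations = 200, seed = i)
    expect_false(mc@exhaustive)
    se <- sqrt(exact@pValue * (1 - exact@pValue) / 200)
    expect_lt(abs(mc@pValue - exact@pValue), 3 * se + 2 / 200)
    expect_gte(mc@pValue, 1 / 201)
  }
})

test_that("pseudo-F arithmetic and edge cases", {
  f <- computePseudoF(0, 3, 2.5, 10)
  expect_equal(f$pseudoF, 0)
  expect_error(computePseudoF(1, 0, 1, 5), "degrees of freedom")
  expect_error(computePseudoF(1, 2, 0, 5), "residual mean square")
  expect_error(computePseudoF(-1, 2, 1, 5), "squares")
})

test_that("PERMANOVA decomposes SS additively and respects invariance", {
  cm <- makeRandomCommunity(9, 12, seed = 17)
  dm <- distanceMatrix(cm, "bray_curtis")
  g <- rep(c("a", "b", "c"), each = 3)
  res <- permanovaOneWay(dm, g, nPermutations = 99, seed = 1)
  tab <- res@table
  expect_equal(tab$SS[1] + tab$SS[2], tab$SS[3], tolerance = 1e-10)
  expect_equal(tab$df[1] + tab$df[2], tab$df[3])
  expect_equal(tab$df[3], 8)
  expect_equal(res@pseudoF, tab$MS[1] / tab$MS[2], tolerance = 1e-12)

  # all equal off-diagonal distances: label permutation cannot matter
  eq <- matrix(0.6, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  diag(eq) <- 0
  resEq <- permanovaOneWay(DistanceMatrix(eq, "sorensen"),
                           rep(c("a", "b"), each = 3), 999)
  expect_equal(resEq@pValue, 1)

  expect_error(permanovaOneWay(dm, c("a", rep("b", 8))), "fewer than 2")
})

test_that("PERMANOVA F and exact p match the vegan-based oracle", {
  set.seed(18)
  for (i in 1:3) {
    cm <- makeRandomCommunity(7, 10, seed = 180 + i)
    dm <- distanceMatrix(cm, "bray_curtis")
    g <- c(rep("a", 3), rep("b", 4))
    res <- permanovaOneWay(dm, g, nPermutations = 1000, seed = i)
    expect_true(res@exhaustive)
    expect_equal(res@pseudoF, oracleAdonisF(as.matrix(dm), g),
                 tolerance = 1e-8)
    expect_equal(res@pValue, oraclePermanova2P(as.matrix(dm), g),
                 tolerance = 1e-10)
  }
})

test_that("PERMANOVA on univariate Euclidean data equals classical ANOVA", {
  set.seed(19)
  y <- rnorm(12)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  res <- permanovaOneWay(DistanceMatrix(d, "euclidean"), g, 99, seed = 1)
  fit <- anova(lm(y ~ g))
  expect_equal(res@pseudoF, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(res@table$SS[1], fit$`Sum Sq`[1], tolerance = 1e-10)
  expect_equal(res@table$SS[2], fit$`Sum Sq`[2], tolerance = 1e-10)
})

test_that("pairwise PERMANOVA matches per-pair one-way runs", {
  cm <- makeRandomCommunity(9, 11, seed = 20)
  dm <- distanceMatrix(cm, "bray_curtis")
  g <- rep(c("a", "b", "c"), each = 3)
  pw <- pairwisePermanova(dm, g, nPermutations = 1000, seed = 1)
  expect_equal(nrow(pw), 3L)
  for (j in seq_len(nrow(pw))) {
    keep <- which(g %in% c(pw$groupA[j], pw$groupB[j]))
    one <- permanovaOneWay(subsetSamples(dm, keep), g[keep], 1000)
    expect_true(one@exhaustive)  # C(6,3) = 20 arrangements
    expect_equal(pw$pseudoF[j], one@pseudoF, tolerance = 1e-12)
    expect_equal(pw$pValue[j], one@pValue, tolerance = 1e-12)
  }
  # two groups total: the single pair equals the one-way test
  g2 <- rep(c("a", "b"), c(4, 5))
  pw2 <- pairwisePermanova(dm, g2, nPermutations = 1000, seed = 1)
  one2 <- permanovaOneWay(dm, g2, 1000)
  expect_equal(nrow(pw2), 1L)
  expect_equal(pw2$pseudoF, one2@pseudoF)
  expect_equal(pw2$pValue, one2@pValue)
  # Holm adjustment never decreases a p-value
  pwh <- pairwisePermanova(dm, g, 1000, seed = 1, correction = "holm")
  expect_true(all(pwh$pAdjusted >= pwh$pValue - 1e-12))
})

test_that("Mantel r matches hand Pearson and exact enumeration", {
  # 4x4 matrices with hand-listed lower triangles (6 pairs)
  xt <- c(0.2, 0.5, 0.4, 0.3, 0.6, 0.1)
  yt <- c(1.0, 2.1, 1.7, 1.2, 2.4, 0.8)
  mk <- function(tri) {
    m <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
    m[lower.tri(m)] <- tri
    m + t(m)
  }
  dx <- DistanceMatrix(mk(xt), "sorensen")
  dy <- DistanceMatrix(mk(yt), "euclidean")
  res <- mantelTest(dx, dy, nPermutations = 1000)
  # Pearson r written out from its definition
  rHand <- sum((xt - mean(xt)) * (yt - mean(yt))) /
    sqrt(sum((xt - mean(xt))^2) * sum((yt - mean(yt))^2))
  expect_equal(res@r, rHand, tolerance = 1e-12)
  expect_true(res@exhaustive)
  expect_equal(res@nPermutations, 24L)
  # exact p by enumerating all 24 relabelings with the oracle generator
  ym <- mk(yt)
  rs <- vapply(oraclePermutations(4), function(p) {
    yp <- ym[p, p]
    stats::cor(xt, yp[lower.tri(yp)])
  }, numeric(1))
  expect_equal(res@pValue, mean(rs >= res@r - 1e-12), tolerance = 1e-12)

  # affine relation: r = 1 regardless of scale and offset
  dyAff <- DistanceMatrix(mk(0.3 + 2 * xt), "euclidean")
  expect_equal(mantelTest(dx, dyAff, 100)@r, 1, tolerance = 1e-12)
  # degenerate: constant triangle
  expect_error(mantelTest(dx, DistanceMatrix(mk(rep(0.5, 6))), 100),
               "zero variance")
})

test_that("Mantel agrees with vegan on a larger instance", {
  cm <- makeRandomCommunity(12, 15, seed = 21)
  set.seed(22)
  ev <- matrix(rnorm(24), 12, 2,
               dimnames = list(sampleNames(cm), c("v1", "v2")))
  dx <- distanceMatrix(cm, "sorensen")
  dy <- distanceMatrix(EnvironmentTable(ev))
  res <- mantelTest(dx, dy, nPermutations = 999, seed = 4)
  vg <- vegan::mantel(stats::as.dist(as.matrix(dx)),
                      stats::as.dist(as.matrix(dy)), permutations = 999)
  expect_equal(res@r, vg$statistic, tolerance = 1e-10)
  expect_lt(abs(res@pValue - vg$signif), 0.05)
})

test_that("partial Mantel residualizes correctly", {
  set.seed(23)
  n <- 7
  mkd <- function(v) {
    m <- as.matrix(dist(v))
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    DistanceMatrix(m, "euclidean")
  }
  v <- rnorm(n)
  z <- rnorm(n)
  dx <- mkd(v)
  dz <- mkd(z)
  # dy = dx with dz pure noise: partial r stays ~1
  r1 <- partialMantelTest(dx, dx, dz, nPermutations = 500, seed = 1)
  expect_gt(r1@r, 0.99)
  # dy = dz exactly: residualization removes all signal
  r0 <- partialMantelTest(dx, dz, dz, nPermutations = 500, seed = 1)
  expect_lt(abs(r0@r), 1e-8)

  # brute-force two-stage regression oracle on a random triple
  dy <- mkd(rnorm(n) + 0.5 * z)
  res <- partialMantelTest(dx, dy, dz, nPermutations = 500, seed = 2)
  tri <- function(d) as.matrix(d)[lower.tri(as.matrix(d))]
  rx <- residuals(lm(tri(dx) ~ tri(dz)))
  ry <- residuals(lm(tri(dy) ~ tri(dz)))
  expect_equal(res@r, cor(rx, ry), tolerance = 1e-10)
})

test_that("permutation p-values are invariant to sample reordering", {
  cm <- makeRandomCommunity(7, 10, seed = 24)
  dm <- distanceMatrix(cm, "bray_curtis")
  g <- c("a", "a", "a", "b", "b", "b", "b")
  res <- permanovaOneWay(dm, g, 1000)
  perm <- c(4, 1, 6, 2, 7, 3, 5)
  res2 <- permanovaOneWay(subsetSamples(dm, perm), g[perm], 1000)
  expect_true(res@exhaustive && res2@exhaustive)
  expect_equal(res@pseudoF, res2@pseudoF, tolerance = 1e-10)
  expect_equal(res@pValue, res2@pValue, tolerance = 1e-10)
})
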