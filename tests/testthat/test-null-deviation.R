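# Null model: occurrence weights, randomized assemblages, group beta,
# null deviation and its replicate simulations.

test_that("occurrence frequencies count occupied samples per species", {
  cm <- makePresenceCommunity(
    list(c(1, 2, 3), c(1, 3), c(1, 3, 4), c(1, 2)), 5)
  w <- occurrenceFrequencies(cm)
  expect_equal(unname(w), c(1, 0.5, 0.75, 0.25, 0))
  # zero-weight species are excluded from the randomization pool
  rnd <- randomizeAssemblage(cm, nullModelConfig(seed = 1))
  expect_equal(unname(colSums(counts(rnd))[5]), 0)
})

test_that("randomized assemblages preserve richness and pool on every draw", {
  for (s in 1:10) {
    cm <- makeRandomCommunity(6, 12, seed = 100 + s, lambda = 1)
    rnd <- randomizeAssemblage(cm, nullModelConfig(seed = s))
    expect_true(all(counts(rnd) %in% c(0, 1)))
    expect_equal(rowSums(counts(rnd) > 0), rowSums(counts(cm) > 0))
    pool <- occurrenceFrequencies(cm) > 0
    expect_true(all(counts(rnd)[, !pool] == 0))
    expect_identical(sampleData(rnd), sampleData(cm))
  }
  # fixed seed: bit-identical draws
  cm <- makeRandomCommunity(5, 10, seed = 11)
  r1 <- randomizeAssemblage(cm, nullModelConfig(seed = 42))
  r2 <- randomizeAssemblage(cm, nullModelConfig(seed = 42))
  expect_identical(counts(r1), counts(r2))
})

test_that("a sample at pool richness receives the full pool; beyond errors", {
  cm <- makePresenceCommunity(list(1:4, c(1, 2)), 4)
  rnd <- randomizeAssemblage(cm, nullModelConfig(seed = 2))
  expect_equal(unname(counts(rnd)[1, ]), rep(1, 4))
  # restricting the known pool below a sample's richness is an error
  w <- c(sp1 = 1, sp2 = 1, sp3 = 1, sp4 = 0)
  expect_error(randomizeAssemblage(cm, nullModelConfig(seed = 2), weights = w),
               "exceeds the regional pool")
})

test_that("single-species draws follow the selection weights", {
  # 6000 draws of 1 species under weights proportional to (0.75, 0.25, 0.5)
  n <- 6000
  m <- matrix(0, n, 3, dimnames = list(sprintf("r%04d", 1:n),
                                       c("sp1", "sp2", "sp3")))
  m[, 1] <- 1  # every sample has richness 1
  cm <- CommunityMatrix(m)
  w <- c(sp1 = 0.75, sp2 = 0.25, sp3 = 0.5)
  rnd <- randomizeAssemblage(cm, nullModelConfig(seed = 3), weights = w)
  obs <- colSums(counts(rnd))
  gof <- suppressWarnings(chisq.test(obs, p = w / sum(w)))
  expect_gt(gof$p.value, 0.001)
})

test_that("group beta-diversity is the mean of pairwise dissimilarities", {
  same <- makePresenceCommunity(list(c(1, 2), c(1, 2), c(1, 2)), 4)
  expect_equal(groupBetaDiversity(same, groupVar = NULL), 0)
  disj <- makePresenceCommunity(list(1, 2, 3), 3)
  expect_equal(groupBetaDiversity(disj, groupVar = NULL), 1)

  cm <- makeRandomCommunity(5, 9, seed = 12)
  pa <- counts(binarize(cm))
  expect_equal(groupBetaDiversity(cm, groupVar = NULL), oracleMeanBeta(pa),
               tolerance = 1e-10)
  # grouped access matches manual subsetting
  md <- data.frame(group = c("a", "a", "a", "b", "b"),
                   row.names = sampleNames(cm))
  cmg <- CommunityMatrix(counts(cm), md)
  expect_equal(groupBetaDiversity(cmg, "a"),
               oracleMeanBeta(pa[1:3, ]), tolerance = 1e-10)
  expect_error(groupBetaDiversity(cmg, "c"), "no samples")
  one <- CommunityMatrix(counts(cm), transform(md, group = c("a", "b", "b", "b", "b")))
  expect_error(groupBetaDiversity(one, "a"), "at least 2")
})

test_that("Monte-Carlo null beta matches exhaustive enumeration", {
  # 3 samples of richness 2 from a 4-species pool, equiprobable:
  # the oracle enumerates all C(4,2)^3 = 216 assemblage triples
  cm <- makePresenceCommunity(list(c(1, 2), c(3, 4), c(1, 3)), 4)
  exact <- oracleExhaustiveNullBeta(c(2, 2, 2), 4)
  res <- nullDeviationGroup(cm, config = nullModelConfig(
    4000, "equiprobable", seed = 13), groupVar = NULL)
  se <- res@betaNullSd / sqrt(res@nRandomizations)
  expect_lt(abs(res@betaNullMean - exact), 3 * se)
  expect_equal(res@nullDeviation,
               (res@betaObs - res@betaNullMean) / res@betaNullMean,
               tolerance = 1e-12)
})

test_that("degenerate null models are rejected, not divided by zero", {
  sat <- makePresenceCommunity(list(1:3, 1:3), 3)
  expect_error(nullDeviationGroup(sat, config = nullModelConfig(50, seed = 1),
                                  groupVar = NULL),
               "degenerate")
  empty <- matrix(c(1, 0, 1, 0), 2, 2,
                  dimnames = list(c("s1", "s2"), c("sp1", "sp2")))
  empty[2, ] <- 0
  expect_error(nullDeviationGroup(CommunityMatrix(empty),
                                  config = nullModelConfig(50, seed = 1),
                                  groupVar = NULL),
               "empty sample")
})

test_that("null deviation is reproducible and replicates are consistent", {
  cm <- makeRandomCommunity(6, 14, seed = 14, lambda = 1,
                            metadata = data.frame(
                              group = rep("g1", 6),
                              row.names = sprintf("s%02d", 1:6)))
  cfg <- nullModelConfig(300, seed = 21)
  a <- nullDeviationGroup(cm, "g1", cfg)
  b <- nullDeviationGroup(cm, "g1", cfg)
  expect_identical(a@nullDeviation, b@nullDeviation)
  expect_identical(a@betaNullMean, b@betaNullMean)

  # one replicate equals a direct call at the derived seed (base + 1)
  rep1 <- replicateNullDeviation(cm, nullModelConfig(300, seed = 20),
                                 nReplicates = 1L)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$nullDeviation, a@nullDeviation)
  expect_equal(rep1$seed, 21L)

  # identical base seeds give identical replicate tables
  r1 <- replicateNullDeviation(cm, nullModelConfig(100, seed = 5),
                               nReplicates = 3L)
  r2 <- replicateNullDeviation(cm, nullModelConfig(100, seed = 5),
                               nReplicates = 3L)
  expect_identical(r1, r2)
})

test_that("replicate spread shrinks as randomizations grow", {
  cm <- makeRandomCommunity(8, 16, seed = 15, lambda = 1,
                            metadata = data.frame(
                              group = rep("g1", 8),
                              row.names = sprintf("s%02d", 1:8)))
  few <- replicateNullDeviation(cm, nullModelConfig(25, seed = 8),
                                nReplicates = 6L)
  many <- replicateNullDeviation(cm, nullModelConfig(2000, seed = 8),
                                 nReplicates = 6L)
  expect_lt(sd(many$nullDeviation), sd(few$nullDeviation))
})
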