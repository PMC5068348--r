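# Alpha diversity, pairwise dissimilarities, distance matrices,
# accumulation curves.

test_that("Shannon diversity matches closed forms and hand values", {
  expect_equal(shannonDiversity(c(5)), 0)
  expect_equal(shannonDiversity(c(3, 3, 3, 3)), log(4), tolerance = 1e-12)
  # -sum((i/6) * log(i/6)) for i = 1, 2, 3, worked out by hand
  expect_equal(shannonDiversity(c(1, 2, 3)), 1.0114043, tolerance = 1e-6)
  expect_equal(shannonDiversity(c(2, 2), base = 2), 1)
  expect_error(shannonDiversity(c(0, 0)), "all-zero")
  expect_error(shannonDiversity(c(-1, 2)), "non-negative")
})

test_that("Shannon diversity is maximal at equal abundances", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    x <- rpois(k, 5) + 1
    expect_lte(shannonDiversity(x), log(k) + 1e-12)
  }
})

test_that("species richness counts positive entries", {
  expect_equal(speciesRichness(c(0, 0, 0)), 0)
  expect_equal(speciesRichness(c(1, 0, 7)), 2)
  set.seed(6)
  v <- rbinom(30, 1, 0.4)
  expect_equal(speciesRichness(v), sum(v))
})

test_that("pairwise dissimilarities follow their defining formulas", {
  expect_equal(sorensenBinary(c(1, 1, 0), c(2, 5, 0)), 0)
  expect_equal(sorensenBinary(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_equal(sorensenBinary(c(1, 1, 1, 0), c(1, 1, 0, 1)), 1 / 3,
               tolerance = 1e-12)
  expect_error(sorensenBinary(c(0, 0), c(1, 0)), "empty")

  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(2, 0), c(0, 3)), 1)
  expect_equal(brayCurtis(c(1, 2), c(2, 1)), 1 / 3, tolerance = 1e-12)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "undefined")
})

test_that("Sorensen equals Bray-Curtis on binarized data (exhaustive)", {
  vecs <- expand.grid(rep(list(0:1), 4))
  vecs <- vecs[rowSums(vecs) > 0, ]
  for (i in seq_len(nrow(vecs))) {
    for (j in seq_len(nrow(vecs))) {
      x <- as.numeric(vecs[i, ])
      y <- as.numeric(vecs[j, ])
      expect_equal(sorensenBinary(x, y), brayCurtis(x, y), tolerance = 1e-12)
    }
  }
})

test_that("distanceMatrix agrees with per-pair calls and hand Euclidean", {
  cm <- makeRandomCommunity(5, 7, seed = 7)
  m <- counts(cm)
  for (metric in c("sorensen", "bray_curtis")) {
    dm <- as.matrix(distanceMatrix(cm, metric))
    fun <- if (metric == "sorensen") sorensenBinary else brayCurtis
    for (i in 1:4) for (j in (i + 1):5)
      expect_equal(dm[i, j], fun(m[i, ], m[j, ]), tolerance = 1e-10)
    expect_equal(unname(diag(dm)), rep(0, 5))
    expect_equal(dm, t(dm))
  }

  # Euclidean on standardized variables, against explicit arithmetic
  ev <- matrix(c(1, 2, 3, 4,
                 10, 10, 30, 30), 4, 2,
               dimnames = list(paste0("s", 1:4), c("v1", "v2")))
  env <- EnvironmentTable(ev)
  z <- apply(ev, 2, function(v) (v - mean(v)) / sd(v))
  de <- as.matrix(distanceMatrix(env))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(de[i, j], sqrt(sum((z[i, ] - z[j, ])^2)), tolerance = 1e-10)
  raw <- as.matrix(distanceMatrix(env, standardize = FALSE))
  expect_equal(raw[1, 2], 1)

  # empty samples rejected by name
  bad <- counts(cm)
  bad[2, ] <- 0
  expect_error(distanceMatrix(CommunityMatrix(bad), "sorensen"), "s02")
})

test_that("distance matrices round-trip through delimited text", {
  dm <- distanceMatrix(makeRandomCommunity(4, 6, seed = 8), "bray_curtis")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceMatrix(dm, f)
  back <- readDistanceMatrix(f, metric = "bray_curtis")
  expect_equal(as.matrix(back), as.matrix(dm), tolerance = 1e-12)
  # asymmetric input refused
  writeLines(c("sample,a,b", "a,0,0.5", "b,0.7,0"), f)
  expect_error(readDistanceMatrix(f), "not symmetric")
})

test_that("species accumulation enumerates, converges, and is monotone", {
  # single sample: one-point curve at its richness
  one <- makeRandomCommunity(1, 6, seed = 9)
  c1 <- speciesAccumulation(one, 10)
  expect_equal(c1@meanRichness, speciesRichness(counts(one)[1, ]))
  expect_equal(c1@sdRichness, 0)

  # identical samples: flat curve, sd 0
  m <- matrix(rep(c(1, 0, 2, 1), each = 3), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("sp", 1:4)))
  cFlat <- speciesAccumulation(CommunityMatrix(m), 50)
  expect_equal(cFlat@meanRichness, rep(3, 3))
  expect_equal(cFlat@sdRichness, rep(0, 3))

  # 2 samples: exhaustive over both orderings
  two <- makePresenceCommunity(list(c(1, 2), c(2, 3, 4)), 5)
  c2 <- speciesAccumulation(two, 10)
  expect_true(c2@exhaustive)
  expect_equal(c2@meanRichness[1], (2 + 3) / 2)
  expect_equal(c2@meanRichness[2], 4)

  # monotone mean, endpoint = total richness, reproducible under seed
  cm <- makeRandomCommunity(7, 12, seed = 10, lambda = 1)
  acc <- speciesAccumulation(cm, 200, seed = 3)
  expect_true(all(diff(acc@meanRichness) >= -1e-9))
  expect_equal(acc@meanRichness[7], sum(colSums(counts(cm)) > 0))
  acc2 <- speciesAccumulation(cm, 200, seed = 3)
  expect_identical(acc@meanRichness, acc2@meanRichness)

  # cross-check against vegan's random accumulator
  sv <- suppressMessages(vegan::specaccum(counts(cm), method = "random",
                                          permutations = 500))
  expect_equal(acc@meanRichness, unname(sv$richness), tolerance = 0.15)
})
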