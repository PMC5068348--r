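## Null-model beta-diversity: randomized assemblages drawn from the
## regional species pool under fixed per-sample richness, and the
## null-deviation statistic (beta_obs - beta_null) / beta_null.

# mean pairwise Sorensen among the rows of a 0/1 matrix; the hot path of
# the null model, so computed via one cross-product rather than vegdist
.meanPairwiseSorensenBinary <- function(pa) {
  A <- tcrossprod(pa)          # shared presences a_ij; diagonal = richness
  r <- diag(A)
  ut <- upper.tri(A)
  d <- 1 - 2 * A[ut] / (outer(r, r, "+")[ut])
  mean(d)
}

# draw one randomized assemblage set: for each requested richness k_i, k_i
# species from the pool without replacement, probability proportional to w
# (sequential draws with renormalized weights, R's sample())
# selection weights: user-supplied known regional weights, or estimated
# occurrence frequencies
.resolveWeights <- function(cm, weights) {
  if (is.null(weights)) return(occurrenceFrequencies(cm))
  if (is.null(names(weights)) || !all(speciesNames(cm) %in% names(weights)))
    stop("weights must be named and cover every species of the matrix")
  w <- as.numeric(weights[speciesNames(cm)])
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  names(w) <- speciesNames(cm)
  w
}

.drawAssemblage <- function(richness, w) {
  S <- length(w)
  pa <- matrix(0, length(richness), S)
  for (i in seq_along(richness))
    pa[i, sample.int(S, richness[i], prob = w)] <- 1
  pa
}

#' Regional occurrence frequencies of each species
#'
#' weight_i = (number of samples in which species i occurs) / (number of
#' samples). These are the default selection weights of the null model;
#' species occurring nowhere get weight 0 and are excluded from the
#' regional pool.
#'
#' @param cm a [CommunityMatrix-class] (raw or binarized).
#' @return named numeric vector of weights in \[0, 1\], one per species.
#' @seealso [randomizeAssemblage()], [nullDeviationGroup()]
#' @export
occurrenceFrequencies <- function(cm) {
  m <- counts(cm)
  colSums(m > 0) / nrow(m)
}

#' Randomly assemble communities from the regional species pool
#'
#' Builds a presence-absence matrix in which every sample independently
#' receives exactly its observed species richness, drawn from the regional
#' pool (species occurring anywhere in `cm`) without replacement with
#' probability proportional to the configured weights. Per-sample alpha
#' richness and the regional pool are preserved exactly, so dissimilarity
#' among randomized samples reflects only random membership turnover.
#'
#' @param cm a [CommunityMatrix-class]; every sample must contain at least
#'   one species.
#' @param config a [NullModelConfig-class]; its seed fixes the draw.
#' @param weights optional named per-species selection weights, used when
#'   the regional pool is known a priori; the default estimates them from
#'   `cm` via [occurrenceFrequencies()]. Species with weight 0 are excluded
#'   from the pool.
#' @return A presence-absence [CommunityMatrix-class] with the labels and
#'   metadata of `cm`.
#' @export
randomizeAssemblage <- function(cm, config = nullModelConfig(),
                                weights = NULL) {
  m <- counts(cm)
  w <- .resolveWeights(cm, weights)
  pool <- which(w > 0)
  if (config@weighting == "equiprobable") w[pool] <- 1
  richness <- rowSums(m > 0)
  if (any(richness == 0))
    stop("empty sample(s): ", paste(rownames(m)[richness == 0], collapse = ", "))
  if (any(richness > length(pool)))
    stop("sample richness exceeds the regional pool size")
  pa <- .withSeed(config@seed, .drawAssemblage(richness, w[pool]))
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  out[, pool] <- pa
  CommunityMatrix(out, sampleData(cm))
}

#' Observed beta-diversity of one group of samples
#'
#' Mean of all pairwise dissimilarities among the group's samples.
#'
#' @param cm a [CommunityMatrix-class] whose metadata has a `groupVar`
#'   column.
#' @param group the group label to measure (omit, with `groupVar = NULL`,
#'   to use all samples of `cm`).
#' @param metric "sorensen" (presences; default) or "bray_curtis"
#'   (abundances).
#' @param groupVar metadata column holding group labels (default "group");
#'   NULL treats all of `cm` as one group.
#' @return mean pairwise dissimilarity (single numeric).
#' @export
groupBetaDiversity <- function(cm, group = NULL,
                               metric = c("sorensen", "bray_curtis"),
                               groupVar = "group") {
  metric <- match.arg(metric)
  sub <- .groupSubset(cm, group, groupVar)
  if (nrow(counts(sub)) < 2)
    stop("beta-diversity needs at least 2 samples in group '", group, "'")
  dm <- distanceMatrix(sub, metric)
  mean(.lowerTri(as.matrix(dm)))
}

.groupSubset <- function(cm, group, groupVar) {
  if (is.null(group) || is.null(groupVar)) return(cm)
  md <- sampleData(cm)
  if (!groupVar %in% colnames(md))
    stop("metadata column not found: ", groupVar)
  keep <- as.character(md[[groupVar]]) == as.character(group)
  if (!any(keep)) stop("no samples in group '", group, "'")
  subsetSamples(cm, which(keep))
}

#' Per-sample mean dissimilarity to group-mates
#'
#' Diagnostic companion to the group-level beta-diversity: for each sample,
#' the mean dissimilarity to the other samples of its group.
#'
#' @inheritParams groupBetaDiversity
#' @return named numeric vector, one value per sample of `cm`.
#' @export
sampleMeanDissimilarity <- function(cm, metric = c("sorensen", "bray_curtis"),
                                    groupVar = "group") {
  metric <- match.arg(metric)
  md <- sampleData(cm)
  if (!groupVar %in% colnames(md))
    stop("metadata column not found: ", groupVar)
  out <- setNames(rep(NA_real_, nrow(counts(cm))), sampleNames(cm))
  for (g in unique(as.character(md[[groupVar]]))) {
    idx <- which(as.character(md[[groupVar]]) == g)
    if (length(idx) < 2) next
    d <- as.matrix(distanceMatrix(subsetSamples(cm, idx), metric))
    out[idx] <- rowSums(d) / (length(idx) - 1)
  }
  out
}

#' Null deviation of one group's beta-diversity
#'
#' Computes the observed mean pairwise Sorensen dissimilarity among the
#' group's samples, estimates its null expectation from `nRandomizations`
#' randomly assembled communities (each preserving per-sample richness and
#' the regional pool of `cm`, species drawn with probability proportional
#' to regional occurrence frequency by default), and returns the null
#' deviation (beta_obs - beta_null) / beta_null. Values near 0 indicate
#' compositions no more or less dissimilar than random draws from the pool
#' (stochastic assembly); values toward +/-1 indicate deterministic
#' structuring.
#'
#' The regional pool is taken from all samples of `cm`, so pass the
#' community fraction being analysed (e.g. the aboveground samples only),
#' not the pooled dataset.
#'
#' @param cm a [CommunityMatrix-class] (raw counts or presences; binarized
#'   internally).
#' @param group group label within `groupVar`; NULL with `groupVar = NULL`
#'   uses all samples.
#' @param config a [NullModelConfig-class].
#' @param groupVar metadata column holding group labels.
#' @param weights optional named per-species selection weights (known
#'   regional pool); estimated from `cm` by default.
#' @return A [NullDeviationResult-class].
#' @examples
#' m <- matrix(rbinom(60, 1, 0.5) + rbinom(60, 2, 0.3), 6, 10,
#'             dimnames = list(paste0("s", 1:6), paste0("sp", 1:10)))
#' m[rowSums(m) == 0, 1] <- 1
#' cm <- CommunityMatrix(m)
#' nullDeviationGroup(cm, config = nullModelConfig(200, seed = 7),
#'                    groupVar = NULL)
#' @export
nullDeviationGroup <- function(cm, group = NULL, config = nullModelConfig(),
                               groupVar = "group", weights = NULL) {
  w <- .resolveWeights(cm, weights)
  pool <- which(w > 0)
  if (config@weighting == "equiprobable") w[pool] <- 1
  sub <- .groupSubset(cm, group, groupVar)
  pa <- (counts(sub) > 0) * 1
  n <- nrow(pa)
  if (n < 2)
    stop("null deviation needs at least 2 samples in group '", group, "'")
  richness <- rowSums(pa)
  if (any(richness == 0))
    stop("empty sample(s): ", paste(rownames(pa)[richness == 0], collapse = ", "))
  if (any(richness > length(pool)))
    stop("sample richness exceeds the regional pool size (",
         length(pool), " species)")
  betaObs <- .meanPairwiseSorensenBinary(pa)
  wPool <- w[pool]
  betaNull <- .withSeed(config@seed, {
    vapply(seq_len(config@nRandomizations), function(r) {
      .meanPairwiseSorensenBinary(.drawAssemblage(richness, wPool))
    }, numeric(1))
  })
  betaNullMean <- mean(betaNull)
  if (betaNullMean == 0)
    stop("degenerate null model: null beta-diversity is 0 ",
         "(every sample saturates the regional pool)")
  new("NullDeviationResult",
      group = if (is.null(group)) "all" else as.character(group),
      betaObs = betaObs,
      betaNullMean = betaNullMean,
      betaNullSd = sd(betaNull),
      nullDeviation = (betaObs - betaNullMean) / betaNullMean,
      nRandomizations = config@nRandomizations,
      seed = config@seed)
}

#' Replicate null-deviation simulations across groups
#'
#' Runs `nReplicates` independent null-deviation estimates for every group,
#' replicate r using seed `config@seed + r` so replicates are reproducible
#' yet independent. The long-format result feeds the label-shuffling
#' permutation test comparing community fractions
#' ([twoGroupPermutationTest()]).
#'
#' @param cm a [CommunityMatrix-class].
#' @param config a [NullModelConfig-class]; its seed is the replicate base
#'   seed.
#' @param groups group labels to analyse; default all levels found in
#'   `groupVar`.
#' @param groupVar metadata column holding group labels.
#' @param nReplicates number of independent simulations per group
#'   (default 5).
#' @return data.frame with columns group, replicate, betaObs, betaNullMean,
#'   betaNullSd, nullDeviation, nRandomizations, seed.
#' @export
replicateNullDeviation <- function(cm, config = nullModelConfig(),
                                   groups = NULL, groupVar = "group",
                                   nReplicates = 5L) {
  if (is.null(groups)) {
    md <- sampleData(cm)
    if (!groupVar %in% colnames(md))
      stop("metadata column not found: ", groupVar)
    groups <- unique(as.character(md[[groupVar]]))
  }
  rows <- list()
  for (g in groups) {
    for (r in seq_len(nReplicates)) {
      cfg <- nullModelConfig(config@nRandomizations, config@weighting,
                             seed = config@seed + r, metric = config@metric)
      res <- nullDeviationGroup(cm, g, cfg, groupVar)
      rows[[length(rows) + 1L]] <- data.frame(
        group = res@group, replicate = r, betaObs = res@betaObs,
        betaNullMean = res@betaNullMean, betaNullSd = res@betaNullSd,
        nullDeviation = res@nullDeviation,
        nRandomizations = res@nRandomizations, seed = res@seed,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a replicate null-deviation table as delimited text
#'
#' @param nd data.frame from [replicateNullDeviation()] (optionally with a
#'   `fraction` column prepended by the caller).
#' @param path output file (".tsv" selects tab separation).
#' @return `path`, invisibly.
#' @export
writeNullDeviationTable <- function(nd, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(nd, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
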