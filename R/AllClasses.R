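#' @import methods
#' @importFrom stats cor dist quantile rlnorm rnorm rpois runif sd var setNames
#' @importFrom utils combn read.table write.table packageVersion
NULL

.checkLabels <- function(x, what) {
  if (is.null(x) || any(is.na(x)) || any(x == ""))
    return(sprintf("missing %s labels", what))
  if (anyDuplicated(x))
    return(sprintf("duplicate %s labels: %s", what,
                   paste(unique(x[duplicated(x)]), collapse = ", ")))
  NULL
}

#' CommunityMatrix: a site-by-species abundance table with sample metadata
#'
#' The central container of the package: a samples x species matrix of
#' non-negative abundances (raw counts, presences, or transformed values)
#' together with a per-sample metadata table. Rows are samples, columns are
#' species; both carry unique labels. Metadata typically holds a `group`
#' column (e.g. chronosequence year) and a `fraction` column (e.g.
#' aboveground/belowground), which grouped analyses such as
#' [nullDeviationGroup()] and [permanovaOneWay()] consume.
#'
#' @slot counts numeric matrix, samples in rows and species in columns, all
#'   entries non-negative and finite, with unique row and column names.
#' @slot sampleData data.frame of per-sample metadata; row names equal
#'   `rownames(counts)` in the same order.
#'
#' @seealso [CommunityMatrix()] for construction, [counts()],
#'   [sampleData()], [binarize()], [logRelativize()]
#' @export
setClass("CommunityMatrix",
  slots = c(counts = "matrix", sampleData = "data.frame"))

setValidity("CommunityMatrix", function(object) {
  m <- object@counts
  if (!is.numeric(m)) return("counts must be numeric")
  msg <- .checkLabels(rownames(m), "sample")
  if (!is.null(msg)) return(msg)
  msg <- .checkLabels(colnames(m), "species")
  if (!is.null(msg)) return(msg)
  if (any(!is.finite(m))) return("counts must be finite (no NA/NaN/Inf)")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    return(sprintf("negative abundance at sample '%s', species '%s'",
                   rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  sd <- object@sampleData
  if (nrow(sd) != nrow(m))
    return("sampleData must have one row per sample")
  if (!identical(rownames(sd), rownames(m)))
    return("sampleData row names must equal counts row names (same order)")
  TRUE
})

#' Construct a CommunityMatrix
#'
#' @param counts numeric matrix of non-negative abundances, samples in rows,
#'   species in columns; row and column names required and unique.
#' @param sampleData optional data.frame of per-sample metadata, with row
#'   names matching (a permutation of) `rownames(counts)`; reordered to the
#'   count-matrix order.
#' @return A [CommunityMatrix-class] object.
#' @examples
#' m <- matrix(c(3, 0, 1, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("spA", "spB")))
#' cm <- CommunityMatrix(m, data.frame(group = c("y0", "y1"),
#'                                     row.names = c("s1", "s2")))
#' counts(cm)
#' @export
CommunityMatrix <- function(counts,
                            sampleData = data.frame(row.names = rownames(counts))) {
  counts <- as.matrix(counts)
  msg <- .checkLabels(rownames(counts), "sample")
  if (is.null(msg)) msg <- .checkLabels(colnames(counts), "species")
  if (!is.null(msg)) stop(msg)
  if (!is.null(sampleData) && nrow(sampleData) == nrow(counts) &&
      !is.null(rownames(sampleData)) &&
      setequal(rownames(sampleData), rownames(counts))) {
    sampleData <- sampleData[rownames(counts), , drop = FALSE]
  }
  new("CommunityMatrix", counts = counts, sampleData = sampleData)
}

#' EnvironmentTable: per-sample environmental covariates
#'
#' Samples x variables matrix of real-valued environmental measurements
#' (soil chemistry, vegetation cover, ...). Sample labels must match the
#' CommunityMatrix they are analysed against; no missing values are allowed
#' after validation.
#'
#' @slot values numeric matrix, samples in rows, variables in columns,
#'   finite entries, unique row and column names.
#' @seealso [EnvironmentTable()], [distanceMatrix()]
#' @export
setClass("EnvironmentTable", slots = c(values = "matrix"))

setValidity("EnvironmentTable", function(object) {
  m <- object@values
  if (!is.numeric(m)) return("values must be numeric")
  msg <- .checkLabels(rownames(m), "sample")
  if (!is.null(msg)) return(msg)
  msg <- .checkLabels(colnames(m), "variable")
  if (!is.null(msg)) return(msg)
  if (any(!is.finite(m))) return("missing or non-finite environmental values")
  TRUE
})

#' Construct an EnvironmentTable
#'
#' @param values numeric matrix (or data.frame) of environmental variables,
#'   samples in rows.
#' @return An [EnvironmentTable-class] object.
#' @export
EnvironmentTable <- function(values) {
  new("EnvironmentTable", values = as.matrix(values))
}

#' DistanceMatrix: labelled pairwise dissimilarities
#'
#' Square symmetric matrix of pairwise dissimilarities with a zero diagonal
#' and the metric recorded. Sorensen and Bray-Curtis entries lie in \[0, 1\];
#' Euclidean entries are unbounded above.
#'
#' @slot values numeric square symmetric matrix, zero diagonal, non-negative,
#'   identical unique row/column labels.
#' @slot metric character scalar naming the dissimilarity used.
#' @seealso [distanceMatrix()], [permanovaOneWay()], [mantelTest()]
#' @export
setClass("DistanceMatrix",
  slots = c(values = "matrix", metric = "character"))

setValidity("DistanceMatrix", function(object) {
  m <- object@values
  if (!is.numeric(m)) return("values must be numeric")
  if (nrow(m) != ncol(m)) return("distance matrix must be square")
  msg <- .checkLabels(rownames(m), "sample")
  if (!is.null(msg)) return(msg)
  if (!identical(rownames(m), colnames(m)))
    return("row and column labels must be identical")
  if (any(!is.finite(m))) return("distances must be finite")
  if (any(m < 0)) return("distances must be non-negative")
  if (any(abs(diag(m)) > 1e-12)) return("diagonal must be zero")
  if (any(abs(m - t(m)) > 1e-8)) return("matrix must be symmetric")
  if (length(object@metric) != 1) return("metric must be a single string")
  if (object@metric %in% c("sorensen", "bray_curtis") && any(m > 1 + 1e-12))
    return(sprintf("%s dissimilarities must be <= 1", object@metric))
  TRUE
})

#' Construct a DistanceMatrix from a square symmetric matrix
#'
#' Most users will build DistanceMatrix objects with [distanceMatrix()];
#' this low-level constructor validates an existing square matrix.
#'
#' @param values square symmetric numeric matrix with zero diagonal and
#'   matching row/column labels.
#' @param metric name of the dissimilarity ("sorensen", "bray_curtis",
#'   "euclidean", or any free-text label).
#' @return A [DistanceMatrix-class] object.
#' @export
DistanceMatrix <- function(values, metric = "unknown") {
  values <- as.matrix(values)
  # symmetrise away numeric fuzz before the strict validity check
  values <- (values + t(values)) / 2
  diag(values) <- 0
  new("DistanceMatrix", values = values, metric = metric)
}

#' AccumulationCurve: sample-based species accumulation
#'
#' Mean and standard deviation of cumulative species richness as samples are
#' accumulated in random order, over a set of orderings. The mean at the
#' full sample count equals the total observed richness.
#'
#' @slot nSamples integer vector 1..N.
#' @slot meanRichness mean cumulative richness at each accumulation step.
#' @slot sdRichness standard deviation of cumulative richness at each step.
#' @slot nOrderings number of sample orderings averaged (all N! orderings
#'   when exhaustively enumerated).
#' @slot exhaustive TRUE when every ordering was enumerated.
#' @seealso [speciesAccumulation()]
#' @export
setClass("AccumulationCurve",
  slots = c(nSamples = "integer", meanRichness = "numeric",
            sdRichness = "numeric", nOrderings = "integer",
            exhaustive = "logical"))

setValidity("AccumulationCurve", function(object) {
  n <- length(object@nSamples)
  if (length(object@meanRichness) != n || length(object@sdRichness) != n)
    return("curve vectors must have equal length")
  if (any(diff(object@meanRichness) < -1e-9))
    return("mean richness must be non-decreasing")
  TRUE
})

#' NullModelConfig: settings for randomized-assemblage generation
#'
#' @slot nRandomizations number of randomly assembled community sets used to
#'   estimate null beta-diversity (default 10000).
#' @slot weighting "occurrence_frequency" (species drawn with probability
#'   proportional to the fraction of samples occupied) or "equiprobable".
#' @slot seed integer seed making the randomization reproducible.
#' @slot metric dissimilarity for beta-diversity; "sorensen" is the headline
#'   choice, "bray_curtis" (on presences) accepted.
#' @seealso [nullModelConfig()], [nullDeviationGroup()]
#' @export
setClass("NullModelConfig",
  slots = c(nRandomizations = "integer", weighting = "character",
            seed = "integer", metric = "character"))

setValidity("NullModelConfig", function(object) {
  if (object@nRandomizations < 1L) return("nRandomizations must be >= 1")
  if (!object@weighting %in% c("occurrence_frequency", "equiprobable"))
    return("weighting must be 'occurrence_frequency' or 'equiprobable'")
  if (!object@metric %in% c("sorensen", "bray_curtis"))
    return("metric must be 'sorensen' or 'bray_curtis'")
  TRUE
})

#' Configure the null model
#'
#' @param nRandomizations number of randomized assemblage sets (default 10000).
#' @param weighting species-selection weights: draws proportional to regional
#'   occurrence frequency (default) or equiprobable.
#' @param seed integer seed (default 1).
#' @param metric beta-diversity dissimilarity; "sorensen" by default.
#' @return A [NullModelConfig-class] object.
#' @examples
#' nullModelConfig(nRandomizations = 1000, seed = 42)
#' @export
nullModelConfig <- function(nRandomizations = 10000L,
                            weighting = c("occurrence_frequency", "equiprobable"),
                            seed = 1L,
                            metric = c("sorensen", "bray_curtis")) {
  new("NullModelConfig",
      nRandomizations = as.integer(nRandomizations),
      weighting = match.arg(weighting),
      seed = as.integer(seed),
      metric = match.arg(metric))
}

#' NullDeviationResult: observed vs null beta-diversity for one group
#'
#' Null deviation is (beta_obs - beta_null) / beta_null, where beta_obs is
#' the mean pairwise dissimilarity among the group's samples and beta_null
#' its expectation over randomly assembled communities that preserve each
#' sample's richness and the regional pool. Values near 0 indicate assembly
#' indistinguishable from random (stochastic); values approaching +/-1
#' indicate strong deviation (deterministic).
#'
#' @slot group group label.
#' @slot betaObs observed mean pairwise dissimilarity.
#' @slot betaNullMean mean null beta-diversity over randomizations.
#' @slot betaNullSd standard deviation of null beta-diversity.
#' @slot nullDeviation (betaObs - betaNullMean) / betaNullMean.
#' @slot nRandomizations,seed provenance of the estimate.
#' @seealso [nullDeviationGroup()], [replicateNullDeviation()]
#' @export
setClass("NullDeviationResult",
  slots = c(group = "character", betaObs = "numeric",
            betaNullMean = "numeric", betaNullSd = "numeric",
            nullDeviation = "numeric", nRandomizations = "integer",
            seed = "integer"))

#' PermutationTestResult: label-shuffling test of a mean difference
#'
#' @slot observedDiff mean(a) - mean(b) on the unshuffled labels.
#' @slot pValue permutation p-value; add-one convention under Monte-Carlo
#'   sampling, exact fraction under exhaustive enumeration.
#' @slot nPermutations number of label arrangements examined.
#' @slot twoSided TRUE for the |difference| (two-sided) test.
#' @slot exhaustive TRUE when all distinct arrangements were enumerated.
#' @seealso [twoGroupPermutationTest()]
#' @export
setClass("PermutationTestResult",
  slots = c(observedDiff = "numeric", pValue = "numeric",
            nPermutations = "integer", twoSided = "logical",
            exhaustive = "logical"))

#' PermanovaResult: one-way PERMANOVA decomposition
#'
#' Sum-of-squares decomposition of a dissimilarity matrix into among-group
#' and residual components, with the pseudo-F ratio and a permutation
#' p-value from shuffling group labels.
#'
#' @slot table data.frame with rows Among, Residual, Total and columns
#'   Source, df, SS, MS.
#' @slot pseudoF MS_among / MS_residual.
#' @slot pValue permutation p-value (upper tail on pseudo-F).
#' @slot nPermutations permutations examined; @slot exhaustive whether all
#'   distinct label arrangements were enumerated.
#' @seealso [permanovaOneWay()], [pairwisePermanova()]
#' @export
setClass("PermanovaResult",
  slots = c(table = "data.frame", pseudoF = "numeric", pValue = "numeric",
            nPermutations = "integer", exhaustive = "logical"))

#' MantelResult: (partial) Mantel correlation between distance matrices
#'
#' @slot r Pearson correlation of the vectorized lower triangles (partial
#'   correlation controlling a third matrix when `partial` is TRUE).
#' @slot pValue upper-tail permutation p-value.
#' @slot nPermutations permutations examined.
#' @slot partial TRUE for a partial Mantel test.
#' @slot controlled label of the controlled matrix ("" when not partial).
#' @slot exhaustive TRUE when all relabelings were enumerated.
#' @seealso [mantelTest()], [partialMantelTest()]
#' @export
setClass("MantelResult",
  slots = c(r = "numeric", pValue = "numeric", nPermutations = "integer",
            partial = "logical", controlled = "character",
            exhaustive = "logical"))

#' AssemblyScenario: design of a synthetic chronosequence dataset
#'
#' Describes a two-fraction, multi-group (chronosequence-year) sampling
#' design and the assembly regime of each fraction. The default mirrors a
#' disturbance chronosequence with 5 years, an aboveground fraction (pool of
#' 23 species, ~11 species per sample, 8 samples per year with 7 in the last
#' year) and a belowground fraction (pool of 20 species, ~5 species per
#' sample, 6 samples per year), 4 species shared between the pools, and a
#' monotone environmental gradient across years.
#'
#' @slot nGroups number of chronosequence groups (years).
#' @slot envGradient per-group environmental value on the niche axis.
#' @slot fractions named list; each element a list with fields `gamma`
#'   (pool size), `samplesPerGroup` (integer vector, one per group),
#'   `richnessMean`, `meanAbundance` (individuals per sample),
#'   `filteringStrength` (0 = neutral), `nicheBreadth`.
#' @slot sharedSpecies number of species shared between the two pools.
#' @slot abundanceShape sdlog of the lognormal species-abundance
#'   distribution of the regional pool.
#' @slot nEnvNoise number of uninformative environmental covariates added
#'   to the environment table.
#' @slot seed integer seed.
#' @seealso [assemblyScenario()], [generateChronosequenceDataset()]
#' @export
setClass("AssemblyScenario",
  slots = c(nGroups = "integer", envGradient = "numeric",
            fractions = "list", sharedSpecies = "integer",
            abundanceShape = "numeric", nEnvNoise = "integer",
            seed = "integer"))

setValidity("AssemblyScenario", function(object) {
  if (length(object@envGradient) != object@nGroups)
    return("envGradient needs one value per group")
  if (length(object@fractions) < 1) return("at least one fraction required")
  for (nm in names(object@fractions)) {
    f <- object@fractions[[nm]]
    need <- c("gamma", "samplesPerGroup", "richnessMean", "meanAbundance",
              "filteringStrength", "nicheBreadth")
    if (!all(need %in% names(f)))
      return(sprintf("fraction '%s' missing fields: %s", nm,
                     paste(setdiff(need, names(f)), collapse = ", ")))
    if (length(f$samplesPerGroup) != object@nGroups)
      return(sprintf("fraction '%s': samplesPerGroup needs one value per group", nm))
    if (f$richnessMean > f$gamma)
      return(sprintf("fraction '%s': mean richness exceeds pool size", nm))
    if (f$filteringStrength < 0)
      return(sprintf("fraction '%s': filteringStrength must be >= 0", nm))
    if (f$nicheBreadth <= 0)
      return(sprintf("fraction '%s': nicheBreadth must be > 0", nm))
  }
  if (object@sharedSpecies < 0 ||
      (length(object@fractions) >= 2 &&
       object@sharedSpecies > min(vapply(object@fractions, function(f) f$gamma, 0))))
    return("sharedSpecies must be between 0 and the smaller pool size")
  TRUE
})

#' SyntheticDataset: simulated community, environment, and ground truth
#'
#' @slot community [CommunityMatrix-class] with `group` and `fraction`
#'   metadata columns.
#' @slot environment [EnvironmentTable-class] carrying the gradient plus
#'   noise covariates.
#' @slot truth list of the generating parameters (scenario echo, regional
#'   pools, per-fraction regimes).
#' @seealso [generateChronosequenceDataset()]
#' @export
setClass("SyntheticDataset",
  slots = c(community = "CommunityMatrix", environment = "EnvironmentTable",
            truth = "list"))
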