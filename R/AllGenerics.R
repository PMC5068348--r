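#' @importFrom BiocGenerics counts
NULL

#' Extract the abundance matrix
#'
#' @param object a [CommunityMatrix-class].
#' @param ... ignored.
#' @return numeric matrix, samples in rows, species in columns.
#' @export
setMethod("counts", "CommunityMatrix", function(object, ...) object@counts)

#' Per-sample metadata of a CommunityMatrix
#'
#' @param object a [CommunityMatrix-class].
#' @param value replacement data.frame with row names matching the samples.
#' @return data.frame of metadata, rows aligned with `sampleNames(object)`.
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname sampleData
#' @export
setMethod("sampleData", "CommunityMatrix", function(object) object@sampleData)

#' @rdname sampleData
#' @export
setGeneric("sampleData<-", function(object, value) standardGeneric("sampleData<-"))

#' @rdname sampleData
#' @export
setMethod("sampleData<-", "CommunityMatrix", function(object, value) {
  value <- as.data.frame(value)
  if (setequal(rownames(value), rownames(object@counts)))
    value <- value[rownames(object@counts), , drop = FALSE]
  object@sampleData <- value
  validObject(object)
  object
})

#' Sample and species labels
#'
#' @param object a [CommunityMatrix-class], [EnvironmentTable-class] or
#'   [DistanceMatrix-class].
#' @return character vector of labels.
#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))

#' @rdname sampleNames
#' @export
setMethod("sampleNames", "CommunityMatrix", function(object) rownames(object@counts))

#' @rdname sampleNames
#' @export
setMethod("sampleNames", "EnvironmentTable", function(object) rownames(object@values))

#' @rdname sampleNames
#' @export
setMethod("sampleNames", "DistanceMatrix", function(object) rownames(object@values))

#' Species labels of a CommunityMatrix
#'
#' @param object a [CommunityMatrix-class].
#' @return character vector of species labels.
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "CommunityMatrix", function(object) colnames(object@counts))

#' Environmental value matrix
#'
#' @param object an [EnvironmentTable-class].
#' @return numeric matrix, samples in rows, variables in columns.
#' @export
setGeneric("envValues", function(object) standardGeneric("envValues"))

#' @rdname envValues
#' @export
setMethod("envValues", "EnvironmentTable", function(object) object@values)

#' Coerce a DistanceMatrix to a base matrix or dist
#'
#' @param x a [DistanceMatrix-class].
#' @param ... ignored.
#' @return `as.matrix` returns the square symmetric matrix; `as.dist` the
#'   lower-triangle "dist" object.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

#' Subset objects to a set of samples
#'
#' Species (columns) are retained even if absent from the kept samples, so
#' that the regional pool of a subset is recomputed explicitly by
#' [occurrenceFrequencies()] rather than silently shrunk.
#'
#' @param object a [CommunityMatrix-class], [EnvironmentTable-class] or
#'   [DistanceMatrix-class].
#' @param samples character vector of sample labels (or logical/integer index).
#' @return object of the same class restricted to `samples`.
#' @export
setGeneric("subsetSamples", function(object, samples) standardGeneric("subsetSamples"))

#' @rdname subsetSamples
#' @export
setMethod("subsetSamples", "CommunityMatrix", function(object, samples) {
  CommunityMatrix(object@counts[samples, , drop = FALSE],
                  object@sampleData[samples, , drop = FALSE])
})

#' @rdname subsetSamples
#' @export
setMethod("subsetSamples", "EnvironmentTable", function(object, samples) {
  EnvironmentTable(object@values[samples, , drop = FALSE])
})

#' @rdname subsetSamples
#' @export
setMethod("subsetSamples", "DistanceMatrix", function(object, samples) {
  DistanceMatrix(object@values[samples, samples, drop = FALSE], object@metric)
})

setMethod("show", "CommunityMatrix", function(object) {
  cat(sprintf("CommunityMatrix: %d samples x %d species\n",
              nrow(object@counts), ncol(object@counts)))
  cat(sprintf("  total abundance: %g; occupied cells: %.1f%%\n",
              sum(object@counts), 100 * mean(object@counts > 0)))
  if (ncol(object@sampleData))
    cat("  metadata:", paste(colnames(object@sampleData), collapse = ", "), "\n")
})

setMethod("show", "EnvironmentTable", function(object) {
  cat(sprintf("EnvironmentTable: %d samples x %d variables (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(utils::head(colnames(object@values), 5), collapse = ", ")))
})

setMethod("show", "DistanceMatrix", function(object) {
  v <- object@values[lower.tri(object@values)]
  cat(sprintf("DistanceMatrix (%s): %d samples; range [%.3f, %.3f]\n",
              object@metric, nrow(object@values),
              if (length(v)) min(v) else 0, if (length(v)) max(v) else 0))
})

setMethod("show", "NullDeviationResult", function(object) {
  cat(sprintf("Null deviation for group '%s'\n", object@group))
  cat(sprintf("  beta_obs = %.4f, beta_null = %.4f (sd %.4f)\n",
              object@betaObs, object@betaNullMean, object@betaNullSd))
  cat(sprintf("  null deviation = %.4f  [%d randomizations, seed %d]\n",
              object@nullDeviation, object@nRandomizations, object@seed))
})

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("%s permutation test of mean difference\n",
              if (object@twoSided) "Two-sided" else "One-sided"))
  cat(sprintf("  observed difference = %.4f, P = %.4g (%s, %d arrangements)\n",
              object@observedDiff, object@pValue,
              if (object@exhaustive) "exhaustive" else "Monte-Carlo",
              object@nPermutations))
})

setMethod("show", "PermanovaResult", function(object) {
  cat("One-way PERMANOVA\n")
  tab <- object@table
  tab$SS <- round(tab$SS, 4)
  tab$MS <- round(tab$MS, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("  pseudo-F = %.4f, P = %.4g (%s, %d permutations)\n",
              object@pseudoF, object@pValue,
              if (object@exhaustive) "exhaustive" else "Monte-Carlo",
              object@nPermutations))
})

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("%s test: r = %.4f, P = %.4g (%d permutations%s)\n",
              if (object@partial)
                sprintf("Partial Mantel (controlling %s)", object@controlled)
              else "Mantel",
              object@r, object@pValue, object@nPermutations,
              if (object@exhaustive) ", exhaustive" else ""))
})

setMethod("show", "AssemblyScenario", function(object) {
  cat(sprintf("AssemblyScenario: %d groups, env gradient [%.2f, %.2f], seed %d\n",
              object@nGroups, min(object@envGradient), max(object@envGradient),
              object@seed))
  for (nm in names(object@fractions)) {
    f <- object@fractions[[nm]]
    cat(sprintf("  %s: pool %d spp, ~%.1f spp/sample, samples/group %s, filtering %.2f\n",
                nm, f$gamma, f$richnessMean,
                paste(f$samplesPerGroup, collapse = "/"), f$filteringStrength))
  }
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset\n")
  show(object@community)
  show(object@environment)
})

#' Components of a SyntheticDataset
#'
#' @param object a [SyntheticDataset-class].
#' @return `community()` the [CommunityMatrix-class]; `envTable()`
#'   the [EnvironmentTable-class]; `truth()` the generating-parameter list.
#' @export
setGeneric("community", function(object) standardGeneric("community"))

#' @rdname community
#' @export
setMethod("community", "SyntheticDataset", function(object) object@community)

#' @rdname community
#' @export
setGeneric("envTable", function(object) standardGeneric("envTable"))

#' @rdname community
#' @export
setMethod("envTable", "SyntheticDataset", function(object) object@environment)

#' @rdname community
#' @export
setGeneric("truth", function(object) standardGeneric("truth"))

#' @rdname community
#' @export
setMethod("truth", "SyntheticDataset", function(object) object@truth)
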