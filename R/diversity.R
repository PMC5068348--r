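## Alpha diversity, pairwise dissimilarities, distance matrices, and
## sample-based species accumulation.

#' Shannon diversity of one sample
#'
#' H' = -sum(p_i * log(p_i)) over species with positive abundance, with
#' p_i the relative abundance. Natural log (nats) by default.
#'
#' @param x non-negative abundance vector with at least one positive entry.
#' @param base logarithm base; `exp(1)` (default) gives nats.
#' @return H' as a single numeric value.
#' @examples
#' shannonDiversity(c(3, 3, 3, 3))  # log(4)
#' @export
shannonDiversity <- function(x, base = exp(1)) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  tot <- sum(x)
  if (tot == 0) stop("Shannon diversity is undefined for an all-zero sample")
  p <- x[x > 0] / tot
  -sum(p * log(p, base = base))
}

#' Species richness of one sample
#'
#' @param x non-negative abundance vector.
#' @return number of species with positive abundance.
#' @export
speciesRichness <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  sum(x > 0)
}

#' Sorensen-Czekanowski binary dissimilarity between two samples
#'
#' With a species shared, b unique to `x`, c unique to `y`:
#' d = 1 - 2a / (2a + b + c). Abundances are reduced to presences first.
#'
#' @param x,y abundance or presence vectors of equal length, each with at
#'   least one presence.
#' @return dissimilarity in \[0, 1\].
#' @examples
#' sorensenBinary(c(1, 1, 1, 0), c(1, 1, 0, 1))  # a=2,b=1,c=1 -> 1/3
#' @export
sorensenBinary <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  px <- x > 0
  py <- y > 0
  if (!any(px) || !any(py))
    stop("Sorensen dissimilarity is undefined for an empty sample")
  a <- sum(px & py)
  b <- sum(px & !py)
  c <- sum(!px & py)
  1 - 2 * a / (2 * a + b + c)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' d = sum(|x_i - y_i|) / sum(x_i + y_i).
#'
#' @param x,y non-negative abundance vectors of equal length with positive
#'   totals.
#' @return dissimilarity in \[0, 1\].
#' @examples
#' brayCurtis(c(1, 2), c(2, 1))  # 2/6
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0)
    stop("Bray-Curtis dissimilarity is undefined for two empty samples")
  sum(abs(x - y)) / tot
}

#' Pairwise distance matrix of a community or environment table
#'
#' For community matrices, "sorensen" (presence-absence Sorensen-Czekanowski,
#' binarization applied internally) and "bray_curtis" are computed through
#' \pkg{vegan}'s `vegdist`; any sample with no occurrences is rejected by
#' name, since both dissimilarities are undefined for empty samples. For
#' environment tables, "euclidean" distances are computed after
#' z-standardizing each variable (heterogeneous units), unless
#' `standardize = FALSE`.
#'
#' @param object a [CommunityMatrix-class] or [EnvironmentTable-class].
#' @param metric "sorensen" (default) or "bray_curtis" for communities; "euclidean"
#'   for environment tables (also accepted for a CommunityMatrix).
#' @param standardize z-standardize environmental variables before the
#'   Euclidean distance (default TRUE).
#' @param ... passed on between methods.
#' @return A [DistanceMatrix-class].
#' @examples
#' m <- matrix(c(1, 0, 2, 3, 1, 0), 2, 3, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' distanceMatrix(CommunityMatrix(m), "bray_curtis")
#' @export
setGeneric("distanceMatrix",
  function(object, metric = NULL, ...) standardGeneric("distanceMatrix"))

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "CommunityMatrix",
  function(object, metric = NULL, ...) {
    metric <- match.arg(metric, c("sorensen", "bray_curtis", "euclidean"))
    m <- counts(object)
    if (metric %in% c("sorensen", "bray_curtis")) {
      empty <- rowSums(m) == 0
      if (any(empty))
        stop("all-zero sample(s) not allowed under ", metric, ": ",
             paste(rownames(m)[empty], collapse = ", "))
      d <- if (metric == "sorensen")
        vegan::vegdist(m, method = "bray", binary = TRUE)
      else
        vegan::vegdist(m, method = "bray", binary = FALSE)
    } else {
      d <- dist(m, method = "euclidean")
    }
    DistanceMatrix(as.matrix(d), metric)
  })

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "EnvironmentTable",
  function(object, metric = NULL, standardize = TRUE, ...) {
    metric <- metric %||% "euclidean"
    if (!identical(metric, "euclidean"))
      stop("environment tables support the euclidean metric only")
    m <- envValues(object)
    if (standardize) {
      sds <- apply(m, 2L, sd)
      if (any(sds == 0))
        stop("constant environmental variable(s) cannot be standardized: ",
             paste(colnames(m)[sds == 0], collapse = ", "))
      m <- scale(m)
    }
    DistanceMatrix(as.matrix(dist(m)), "euclidean")
  })

#' Write / read a DistanceMatrix as square labelled delimited text
#'
#' @param dm a [DistanceMatrix-class].
#' @param path file path (".tsv" selects tab separation).
#' @param metric metric label to attach on read.
#' @return `writeDistanceMatrix` returns `path` invisibly;
#'   `readDistanceMatrix` a [DistanceMatrix-class] (symmetry is enforced by
#'   the class validity check).
#' @export
writeDistanceMatrix <- function(dm, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(sample = sampleNames(dm), as.matrix(dm), check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path, metric = "unknown") {
  df <- .readDelim(path)
  m <- as.matrix(df)
  if (max(abs(m - t(m))) > 1e-8)
    stop("matrix read from ", path, " is not symmetric")
  DistanceMatrix(m, metric)
}

#' Sample-based species accumulation curve
#'
#' Cumulative species richness as samples are added in random order,
#' averaged over `nOrderings` orderings (all N! orderings are enumerated
#' when N! <= nOrderings). The mean at the full sample count equals total
#' observed richness, and the mean curve is monotone non-decreasing.
#'
#' @param cm a [CommunityMatrix-class].
#' @param nOrderings number of random sample orderings (default 1000).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return An [AccumulationCurve-class].
#' @export
speciesAccumulation <- function(cm, nOrderings = 1000L, seed = NULL) {
  pa <- counts(cm) > 0
  n <- nrow(pa)
  exhaustive <- factorial(n) <= nOrderings
  orderings <- if (exhaustive) {
    .allPermutations(n)
  } else {
    .withSeed(seed, replicate(nOrderings, sample.int(n), simplify = FALSE))
  }
  rich <- vapply(orderings, function(ord) {
    seen <- rep(FALSE, ncol(pa))
    out <- numeric(n)
    for (k in seq_len(n)) {
      seen <- seen | pa[ord[k], ]
      out[k] <- sum(seen)
    }
    out
  }, numeric(n))
  rich <- matrix(rich, nrow = n)  # steps x orderings
  new("AccumulationCurve",
      nSamples = seq_len(n),
      meanRichness = rowMeans(rich),
      sdRichness = if (length(orderings) < 2L) rep(0, n) else apply(rich, 1L, sd),
      nOrderings = length(orderings),
      exhaustive = exhaustive)
}
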