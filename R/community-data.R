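## Readers/writers for the package's delimited formats and the standard
## abundance transforms applied before dissimilarity analyses.

.readDelim <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  read.table(path, sep = sep, header = TRUE, row.names = 1L,
             check.names = FALSE, stringsAsFactors = FALSE, comment.char = "")
}

#' Read a site-by-species table from delimited text
#'
#' Expects one header row of species labels and one leading column of sample
#' labels (CSV or TSV, auto-detected). Set `samplesInRows = FALSE` for files
#' written transposed (species in rows).
#'
#' @param path file path of the delimited table.
#' @param samplesInRows TRUE (default) when rows are samples; FALSE when the
#'   file is transposed.
#' @param sampleData optional data.frame of per-sample metadata, or a path to
#'   a delimited metadata table with a leading sample-label column.
#' @param sep field separator; auto-detected ("," or tab) when NULL.
#' @return A validated [CommunityMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample,spA,spB", "s1,3,0", "s2,1,2"), f)
#' readCommunityTable(f)
#' @seealso [writeCommunityTable()], [readEnvironmentTable()]
#' @export
readCommunityTable <- function(path, samplesInRows = TRUE, sampleData = NULL,
                               sep = NULL) {
  df <- .readDelim(path, sep)
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric entries in column(s): ",
         paste(colnames(df)[bad], collapse = ", "))
  m <- as.matrix(df)
  if (!samplesInRows) m <- t(m)
  if (is.character(sampleData)) {
    sampleData <- .readDelim(sampleData)
  }
  if (is.null(sampleData))
    sampleData <- data.frame(row.names = rownames(m))
  CommunityMatrix(m, sampleData)
}

#' Write a CommunityMatrix (and optionally its metadata) to delimited text
#'
#' @param cm a [CommunityMatrix-class].
#' @param path output file; extension ".tsv" selects tab separation,
#'   anything else comma.
#' @param metadataPath optional path for the sample-metadata table.
#' @return `path`, invisibly.
#' @export
writeCommunityTable <- function(cm, path, metadataPath = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(sample = rownames(counts(cm)), counts(cm),
                   check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(metadataPath)) {
    md <- data.frame(sample = rownames(counts(cm)), sampleData(cm),
                     check.names = FALSE)
    write.table(md, metadataPath, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an environment table from delimited text
#'
#' @param path delimited file, samples in rows, one leading sample-label
#'   column, numeric variables in the remaining columns.
#' @param sep field separator; auto-detected when NULL.
#' @return An [EnvironmentTable-class].
#' @export
readEnvironmentTable <- function(path, sep = NULL) {
  df <- .readDelim(path, sep)
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric environmental column(s): ",
         paste(colnames(df)[bad], collapse = ", "))
  EnvironmentTable(as.matrix(df))
}

#' Write an EnvironmentTable to delimited text
#'
#' @param env an [EnvironmentTable-class].
#' @param path output file (".tsv" selects tab separation).
#' @return `path`, invisibly.
#' @export
writeEnvironmentTable <- function(env, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(sample = rownames(envValues(env)), envValues(env),
                   check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool temporal replicates into one grand sample per unit
#'
#' Sums counts across repeated sampling events (e.g. June and August
#' collections) of the same sampling unit (e.g. focal tree), yielding one
#' grand sample per unit. The event column is dropped from the metadata; all
#' other metadata columns must agree within a unit.
#'
#' @param cm a [CommunityMatrix-class] of raw abundances whose metadata
#'   contains both labels.
#' @param eventLabel metadata column naming the sampling event.
#' @param unitLabel metadata column naming the unit to pool into.
#' @return A [CommunityMatrix-class] with one sample per unit, named by the
#'   unit label.
#' @examples
#' m <- matrix(c(1, 0, 0, 3, 2, 1), 2, 3, byrow = TRUE,
#'             dimnames = list(c("T1_jun", "T1_aug"), c("a", "b", "c")))
#' cm <- CommunityMatrix(m, data.frame(tree = c("T1", "T1"),
#'                                     event = c("jun", "aug"),
#'                                     row.names = rownames(m)))
#' counts(binTemporalReplicates(cm, "event", "tree"))
#' @export
binTemporalReplicates <- function(cm, eventLabel = "event", unitLabel = "unit") {
  md <- sampleData(cm)
  for (lab in c(eventLabel, unitLabel))
    if (!lab %in% colnames(md))
      stop("metadata column not found: ", lab)
  unit <- as.character(md[[unitLabel]])
  pooled <- rowsum(counts(cm), group = unit, reorder = FALSE)
  keep <- setdiff(colnames(md), c(eventLabel, unitLabel))
  outMd <- data.frame(row.names = rownames(pooled))
  for (col in keep) {
    vals <- tapply(as.character(md[[col]]), unit, function(v) unique(v))
    nv <- vapply(vals, length, integer(1))
    if (any(nv > 1))
      stop(sprintf("metadata column '%s' conflicts within unit(s): %s",
                   col, paste(names(vals)[nv > 1], collapse = ", ")))
    v <- unlist(vals)[rownames(pooled)]
    if (is.numeric(md[[col]])) v <- as.numeric(v)
    outMd[[col]] <- v
  }
  CommunityMatrix(pooled, outMd)
}

#' Convert abundances to presence-absence
#'
#' Every positive entry becomes 1, zeros stay 0. Required (and applied
#' internally) by the Sorensen dissimilarity and the null model.
#'
#' @param cm a [CommunityMatrix-class].
#' @return A [CommunityMatrix-class] of 0/1 entries with unchanged labels
#'   and metadata. Idempotent.
#' @export
binarize <- function(cm) {
  m <- counts(cm)
  m[] <- as.numeric(m > 0)
  CommunityMatrix(m, sampleData(cm))
}

#' Log-transform and relativize abundances
#'
#' Applies `log10(x + 1)` to every entry, then divides each species column
#' by its maximum transformed value (general relativization by column
#' maximum), putting all species on a common \[0, 1\] scale so that abundant
#' taxa do not dominate Bray-Curtis distances. Columns with no occurrences
#' stay all-zero. `global = TRUE` divides by the single global maximum
#' instead of per-column maxima.
#'
#' @param cm a [CommunityMatrix-class] of raw counts.
#' @param base logarithm base (default 10).
#' @param global relativize by the global maximum rather than per-species
#'   column maxima.
#' @return A [CommunityMatrix-class] with entries in \[0, 1\].
#' @examples
#' m <- matrix(c(0, 9, 99), 3, 1, dimnames = list(paste0("s", 1:3), "spA"))
#' counts(logRelativize(CommunityMatrix(m)))  # 0, 0.5, 1
#' @export
logRelativize <- function(cm, base = 10, global = FALSE) {
  m <- log(counts(cm) + 1, base = base)
  if (global) {
    mx <- max(m)
    if (mx > 0) m <- m / mx
  } else {
    mx <- apply(m, 2L, max)
    nz <- mx > 0
    m[, nz] <- sweep(m[, nz, drop = FALSE], 2L, mx[nz], "/")
  }
  CommunityMatrix(m, sampleData(cm))
}
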