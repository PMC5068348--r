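## Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random-number stream; seed = NULL uses the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# strict lower-triangle vectorization of a square matrix (column-major,
# the shared convention for Mantel statistics)
.lowerTri <- function(m) m[lower.tri(m)]

# all n! permutations of 1..n as a list; only called for small n
.allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", factorial(n))
  k <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      out[[k]] <- c(i, rest[p])
      k <- k + 1L
    }
  }
  out
}

# number of distinct arrangements of a label multiset: n! / prod(n_g!)
.nArrangements <- function(groupSizes) {
  exp(lgamma(sum(groupSizes) + 1) - sum(lgamma(groupSizes + 1)))
}

# enumerate all distinct assignments of group labels (1..G, with given
# sizes) to positions 1..N; returns a matrix, one assignment per row
.enumerateAssignments <- function(groupSizes) {
  n <- sum(groupSizes)
  rec <- function(positions, sizes) {
    if (length(sizes) == 1L) {
      m <- matrix(0L, 1L, n)
      m[, positions] <- 1L
      return(m)
    }
    g <- length(sizes)
    sets <- combn(positions, sizes[g])
    out <- vector("list", ncol(sets))
    for (j in seq_len(ncol(sets))) {
      taken <- sets[, j]
      subm <- rec(setdiff(positions, taken), sizes[-g])
      subm[, taken] <- g
      out[[j]] <- subm
    }
    do.call(rbind, out)
  }
  rec(seq_len(n), groupSizes)
}

# group labels as a clean factor, with singleton/size checks
.asGroups <- function(groups, n, minSize = 2L) {
  groups <- as.factor(groups)
  if (length(groups) != n)
    stop("group labels must match the number of samples")
  sz <- table(groups)
  if (any(sz < minSize))
    stop("group(s) with fewer than ", minSize, " samples: ",
         paste(names(sz)[sz < minSize], collapse = ", "))
  groups
}
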