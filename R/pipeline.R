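## End-to-end orchestration: load or simulate data, transform, PERMANOVA,
## replicate null deviation, fraction-contrast permutation tests, Mantel
## tests, and the delimited report bundle.

#' Assemble an analysis configuration
#'
#' Either `community` (+ optional `metadata`, `environment`) or `scenario`
#' must be given; paths are read with the package's delimited readers at
#' run time.
#'
#' @param community path to a community table, or a
#'   [CommunityMatrix-class].
#' @param metadata path to a sample-metadata table, or a data.frame
#'   (ignored when `community` is a CommunityMatrix carrying metadata).
#' @param environment path to an environment table, an
#'   [EnvironmentTable-class], or NULL to skip Mantel tests.
#' @param scenario path to a YAML scenario, or an
#'   [AssemblyScenario-class]; simulated data replace file inputs.
#' @param groupVar,fractionVar metadata columns holding the group
#'   (chronosequence year) and community-fraction labels.
#' @param eventVar,unitVar when both are given, temporal replicates are
#'   pooled with [binTemporalReplicates()] before analysis.
#' @param nRandomizations,weighting null-model settings (see
#'   [nullModelConfig()]).
#' @param nReplicates independent null-deviation simulations per group
#'   (default 5).
#' @param nPermutations permutations for PERMANOVA, the null-deviation
#'   contrast and Mantel tests (default 9999).
#' @param outDir output directory for the report bundle (created if
#'   needed); NULL computes results without writing files.
#' @param seed integer master seed; every stage derives its own seed from
#'   it, so a run is reproducible from the manifest alone.
#' @param verbose print stage progress (default TRUE).
#' @return named list (class "analysisConfig").
#' @seealso [runAnalysis()]
#' @export
analysisConfig <- function(community = NULL, metadata = NULL,
                           environment = NULL, scenario = NULL,
                           groupVar = "group", fractionVar = "fraction",
                           eventVar = NULL, unitVar = NULL,
                           nRandomizations = 10000L,
                           weighting = "occurrence_frequency",
                           nReplicates = 5L, nPermutations = 9999L,
                           outDir = NULL, seed = 1L, verbose = TRUE) {
  if (is.null(community) && is.null(scenario))
    stop("either 'community' or 'scenario' must be provided")
  cfg <- list(community = community, metadata = metadata,
              environment = environment, scenario = scenario,
              groupVar = groupVar, fractionVar = fractionVar,
              eventVar = eventVar, unitVar = unitVar,
              nRandomizations = as.integer(nRandomizations),
              weighting = weighting, nReplicates = as.integer(nReplicates),
              nPermutations = as.integer(nPermutations),
              outDir = outDir, seed = as.integer(seed), verbose = verbose)
  class(cfg) <- c("analysisConfig", "list")
  cfg
}

.say <- function(verbose, ...) if (verbose) message(sprintf(...))

.loadInputs <- function(cfg) {
  if (!is.null(cfg$scenario)) {
    sc <- if (is.character(cfg$scenario)) readAssemblyScenario(cfg$scenario)
          else cfg$scenario
    ds <- generateChronosequenceDataset(sc)
    return(list(cm = community(ds), env = envTable(ds)))
  }
  cm <- if (is.character(cfg$community))
    readCommunityTable(cfg$community, sampleData = cfg$metadata)
  else cfg$community
  if (!is.character(cfg$community) && is.data.frame(cfg$metadata))
    sampleData(cm) <- cfg$metadata
  env <- if (is.character(cfg$environment)) readEnvironmentTable(cfg$environment)
         else cfg$environment
  list(cm = cm, env = env)
}

#' Run the full community-assembly analysis
#'
#' Stages, in order: (1) load or simulate inputs; (2) pool temporal
#' replicates when configured; (3) per-sample diversity summary (richness,
#' Shannon H', mean dissimilarity to group-mates); (4) per-fraction one-way
#' PERMANOVA among groups on Bray-Curtis distances of log-transformed,
#' maximum-relativized abundances, with pairwise PERMANOVA only when the
#' one-way p-value is below 0.05; (5) replicate null-deviation simulations
#' per group and fraction; (6) within-group two-sided permutation tests
#' contrasting the null deviations of each fraction pair; (7) Mantel and
#' per-variable partial Mantel tests of community Sorensen distances
#' against environmental Euclidean distances (skipped without an
#' environment table); (8) report bundle and machine-readable manifest
#' written to `outDir` when set.
#'
#' @param config an [analysisConfig()] list.
#' @return invisible list with elements `diversity`, `permanova` (per
#'   fraction: the [PermanovaResult-class], its Table-1-style data.frame,
#'   and any pairwise table), `nullDeviation`, `ndTests`, `mantel`,
#'   `manifest`, and `files` (paths written).
#' @export
runAnalysis <- function(config) {
  stopifnot(inherits(config, "analysisConfig"))
  stage <- "load inputs"
  res <- tryCatch({
    inp <- .loadInputs(config)
    cm <- inp$cm
    env <- inp$env
    .say(config$verbose, "loaded %d samples x %d species",
         nrow(counts(cm)), ncol(counts(cm)))

    if (!is.null(config$eventVar) && !is.null(config$unitVar)) {
      stage <- "temporal binning"
      cm <- binTemporalReplicates(cm, config$eventVar, config$unitVar)
      .say(config$verbose, "binned to %d grand samples", nrow(counts(cm)))
    }

    md <- sampleData(cm)
    if (!config$groupVar %in% colnames(md))
      stop("metadata lacks the group column '", config$groupVar, "'")
    fractions <- if (config$fractionVar %in% colnames(md))
      unique(as.character(md[[config$fractionVar]]))
    else "all"
    fracSamples <- function(f) {
      if (identical(fractions, "all")) seq_len(nrow(md))
      else which(as.character(md[[config$fractionVar]]) == f)
    }

    stage <- "diversity summary"
    diversity <- do.call(rbind, lapply(fractions, function(f) {
      sub <- subsetSamples(cm, fracSamples(f))
      m <- counts(sub)
      data.frame(
        sample = rownames(m), fraction = f,
        group = as.character(sampleData(sub)[[config$groupVar]]),
        richness = apply(m, 1L, speciesRichness),
        shannon = apply(m, 1L, function(x)
          if (sum(x) > 0) shannonDiversity(x) else NA_real_),
        meanDissimToGroup = sampleMeanDissimilarity(sub, "sorensen",
                                                    config$groupVar),
        stringsAsFactors = FALSE, row.names = NULL)
    }))

    stage <- "PERMANOVA"
    permanova <- list()
    for (f in fractions) {
      sub <- subsetSamples(cm, fracSamples(f))
      dm <- distanceMatrix(logRelativize(sub), "bray_curtis")
      grp <- sampleData(sub)[[config$groupVar]]
      one <- permanovaOneWay(dm, grp, config$nPermutations,
                             seed = config$seed + 1000L)
      pw <- NULL
      if (one@pValue < 0.05) {
        pw <- pairwisePermanova(dm, grp, config$nPermutations,
                                seed = config$seed + 2000L)
      }
      permanova[[f]] <- list(oneWay = one,
                             table = permanovaToTable(one, community = f),
                             pairwise = pw)
      .say(config$verbose, "PERMANOVA [%s]: F = %.3f, P = %.4g%s", f,
           one@pseudoF, one@pValue,
           if (is.null(pw)) " (pairwise gate closed)" else "")
    }

    stage <- "null deviation"
    cfgNull <- nullModelConfig(config$nRandomizations, config$weighting,
                               seed = config$seed)
    nullDeviation <- do.call(rbind, lapply(fractions, function(f) {
      .say(config$verbose,
           "null deviation [%s]: %d randomizations x %d replicates",
           f, config$nRandomizations, config$nReplicates)
      nd <- replicateNullDeviation(subsetSamples(cm, fracSamples(f)),
                                   cfgNull, groupVar = config$groupVar,
                                   nReplicates = config$nReplicates)
      cbind(fraction = f, nd, stringsAsFactors = FALSE)
    }))

    stage <- "null-deviation permutation tests"
    ndTests <- NULL
    if (length(fractions) >= 2) {
      prs <- combn(fractions, 2L)
      rows <- list()
      for (g in unique(nullDeviation$group)) {
        for (j in seq_len(ncol(prs))) {
          a <- nullDeviation$nullDeviation[
            nullDeviation$group == g & nullDeviation$fraction == prs[1, j]]
          b <- nullDeviation$nullDeviation[
            nullDeviation$group == g & nullDeviation$fraction == prs[2, j]]
          if (length(a) < 2 || length(b) < 2) next
          tt <- suppressWarnings(
            twoGroupPermutationTest(a, b, config$nPermutations,
                                    seed = config$seed + 3000L + j))
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, fractionA = prs[1, j], fractionB = prs[2, j],
            observedDiff = tt@observedDiff, pValue = tt@pValue,
            nPermutations = tt@nPermutations, exhaustive = tt@exhaustive,
            stringsAsFactors = FALSE)
        }
      }
      ndTests <- do.call(rbind, rows)
    }

    stage <- "Mantel tests"
    mantel <- NULL
    if (!is.null(env)) {
      rows <- list()
      for (f in fractions) {
        idx <- fracSamples(f)
        sub <- subsetSamples(cm, idx)
        dx <- distanceMatrix(sub, "sorensen")
        envSub <- subsetSamples(env, sampleNames(sub))
        vars <- colnames(envValues(envSub))
        dyAll <- distanceMatrix(envSub, "euclidean")
        mt <- mantelTest(dx, dyAll, config$nPermutations,
                         seed = config$seed + 4000L)
        rows[[length(rows) + 1L]] <- data.frame(
          fraction = f, variable = "all", partial = FALSE, r = mt@r,
          pValue = mt@pValue, stringsAsFactors = FALSE)
        if (length(vars) >= 2) {
          for (v in vars) {
            dv <- distanceMatrix(
              EnvironmentTable(envValues(envSub)[, v, drop = FALSE]),
              "euclidean")
            dz <- distanceMatrix(
              EnvironmentTable(envValues(envSub)[, setdiff(vars, v),
                                                 drop = FALSE]),
              "euclidean")
            pm <- partialMantelTest(dx, dv, dz, config$nPermutations,
                                    seed = config$seed + 4000L +
                                      match(v, vars), controlled = "rest")
            rows[[length(rows) + 1L]] <- data.frame(
              fraction = f, variable = v, partial = TRUE, r = pm@r,
              pValue = pm@pValue, stringsAsFactors = FALSE)
          }
        }
        .say(config$verbose, "Mantel [%s]: r = %.3f, P = %.4g", f,
             mt@r, mt@pValue)
      }
      mantel <- do.call(rbind, rows)
    }

    manifest <- list(
      package = "betanull",
      version = as.character(packageVersion("betanull")),
      rVersion = R.version.string,
      seed = config$seed,
      nRandomizations = config$nRandomizations,
      weighting = config$weighting,
      nReplicates = config$nReplicates,
      nPermutations = config$nPermutations,
      groupVar = config$groupVar,
      fractionVar = config$fractionVar,
      fractions = as.list(fractions),
      scenario = if (!is.null(config$scenario) &&
                     !is.character(config$scenario)) "inline" else
                 config$scenario %||% "none",
      community = if (is.character(config$community)) config$community
                  else if (is.null(config$community)) "simulated"
                  else "inline")

    out <- list(diversity = diversity, permanova = permanova,
                nullDeviation = nullDeviation, ndTests = ndTests,
                mantel = mantel, manifest = manifest, files = character())
    if (!is.null(config$outDir)) {
      stage <- "report"
      out$files <- writeReport(out, config$outDir)
    }
    out
  }, error = function(e) {
    stop(sprintf("analysis failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a PermanovaResult as a Table-1-style data.frame
#'
#' Columns: Community, Source, df, SS, MSE, F, P; the F and P entries are
#' filled on the among-group row only.
#'
#' @param res a [PermanovaResult-class].
#' @param community label for the Community column.
#' @return data.frame with the columns above.
#' @export
permanovaToTable <- function(res, community = "") {
  tab <- res@table
  data.frame(
    Community = c(community, "", ""),
    Source = tab$Source,
    df = tab$df,
    SS = tab$SS,
    MSE = tab$MS,
    F = c(res@pseudoF, NA_real_, NA_real_),
    P = c(res@pValue, NA_real_, NA_real_),
    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write the analysis report bundle
#'
#' Writes delimited tables (diversity summary, PERMANOVA tables, null
#' deviations, fraction-contrast tests, Mantel table), a plain-text
#' summary, and a YAML manifest into `outDir`. Empty result components
#' yield header-only tables.
#'
#' @param results list as returned by [runAnalysis()].
#' @param outDir output directory (created recursively).
#' @return character vector of the files written, invisibly.
#' @export
writeReport <- function(results, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  files <- character()
  wr <- function(df, name) {
    path <- file.path(outDir, name)
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(results$diversity %||%
       data.frame(sample = character(), fraction = character(),
                  group = character(), richness = integer(),
                  shannon = numeric(), meanDissimToGroup = numeric()),
     "diversity_summary.csv")
  for (f in names(results$permanova)) {
    wr(results$permanova[[f]]$table, sprintf("permanova_%s.csv", f))
    if (!is.null(results$permanova[[f]]$pairwise))
      wr(results$permanova[[f]]$pairwise,
         sprintf("permanova_pairwise_%s.csv", f))
  }
  wr(results$nullDeviation %||%
       data.frame(fraction = character(), group = character(),
                  replicate = integer(), betaObs = numeric(),
                  betaNullMean = numeric(), betaNullSd = numeric(),
                  nullDeviation = numeric(), nRandomizations = integer(),
                  seed = integer()),
     "null_deviation.csv")
  if (!is.null(results$ndTests)) wr(results$ndTests, "nd_permutation_tests.csv")
  if (!is.null(results$mantel)) wr(results$mantel, "mantel.csv")

  sm <- file.path(outDir, "summary.txt")
  con <- file(sm, "w")
  on.exit(close(con))
  writeLines("Community-assembly inference summary", con)
  writeLines(sprintf("seed: %d", results$manifest$seed), con)
  for (f in names(results$permanova)) {
    one <- results$permanova[[f]]$oneWay
    writeLines(sprintf(
      "PERMANOVA [%s]: pseudo-F = %.3f, P = %.4g (%s)", f, one@pseudoF,
      one@pValue,
      if (is.null(results$permanova[[f]]$pairwise)) "no pairwise tests"
      else "pairwise tests emitted"), con)
  }
  if (!is.null(results$nullDeviation)) {
    agg <- stats::aggregate(nullDeviation ~ fraction,
                            data = results$nullDeviation, FUN = mean)
    for (i in seq_len(nrow(agg)))
      writeLines(sprintf("mean null deviation [%s]: %.4f",
                         agg$fraction[i], agg$nullDeviation[i]), con)
  }
  files <- c(files, sm)

  mf <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(results$manifest, mf)
  files <- c(files, mf)
  invisible(files)
}

#' Plot null deviation by group and fraction
#'
#' Mean replicate null deviation per group for each fraction, with
#' replicate spread as vertical bars; the zero line marks assembly
#' indistinguishable from the null model.
#'
#' @param nullDeviation data.frame with columns fraction, group,
#'   nullDeviation (as produced by [runAnalysis()]).
#' @param path optional PNG path; NULL draws on the active device.
#' @return invisibly, the aggregated means.
#' @export
plotNullDeviation <- function(nullDeviation, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off())
  }
  agg <- stats::aggregate(nullDeviation ~ fraction + group,
                          data = nullDeviation, FUN = mean)
  lo <- stats::aggregate(nullDeviation ~ fraction + group,
                         data = nullDeviation, FUN = min)
  hi <- stats::aggregate(nullDeviation ~ fraction + group,
                         data = nullDeviation, FUN = max)
  groups <- sort(unique(agg$group))
  fracs <- sort(unique(agg$fraction))
  cols <- grDevices::hcl.colors(max(2L, length(fracs)), "Dark 2")
  xs <- seq_along(groups)
  ylim <- range(c(lo$nullDeviation, hi$nullDeviation, 0))
  graphics::plot(NA, xlim = range(xs) + c(-0.2, 0.2), ylim = ylim,
                 xaxt = "n", xlab = "group", ylab = "null deviation")
  graphics::axis(1, at = xs, labels = groups)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  for (i in seq_along(fracs)) {
    off <- (i - (length(fracs) + 1) / 2) * 0.1
    sel <- agg$fraction == fracs[i]
    ord <- match(groups, agg$group[sel])
    graphics::segments(xs + off, lo$nullDeviation[sel][ord],
                       xs + off, hi$nullDeviation[sel][ord], col = cols[i])
    graphics::points(xs + off, agg$nullDeviation[sel][ord], pch = 19,
                     col = cols[i])
    graphics::lines(xs + off, agg$nullDeviation[sel][ord], col = cols[i])
  }
  graphics::legend("topright", legend = fracs, col = cols[seq_along(fracs)],
                   pch = 19, bty = "n")
  invisible(agg)
}
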