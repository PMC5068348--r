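## Synthetic chronosequence communities assembled under controlled
## mixtures of neutral (stochastic) and environmentally filtered
## (deterministic) dynamics, for validating the inference pipeline
## against known ground truth.

#' Construct an AssemblyScenario
#'
#' The defaults mirror a two-fraction disturbance chronosequence: 5 groups
#' (years since tree mortality), an aboveground fraction with a 23-species
#' regional pool, ~11 species per sample and 8 samples per year (7 in the
#' final year), a belowground fraction with a 20-species pool, ~5 species
#' per sample and 6 samples per year, 4 species shared between the pools,
#' and a linear environmental gradient across years. Under the default
#' regimes the aboveground fraction is assembled with environmental
#' filtering (deterministic) and the belowground fraction neutrally
#' (stochastic), the contrast the pipeline is expected to recover.
#'
#' @param nGroups number of chronosequence groups.
#' @param envGradient per-group value on the niche axis (default an even
#'   grid on \[0, 1\]).
#' @param fractions named list of per-fraction designs; see
#'   [AssemblyScenario-class] for the required fields.
#' @param sharedSpecies species shared between the two fraction pools
#'   (default 4; only meaningful with exactly two fractions).
#' @param abundanceShape sdlog of the lognormal regional
#'   species-abundance distribution (default 1).
#' @param nEnvNoise uninformative covariates appended to the environment
#'   table (default 4).
#' @param seed integer seed (default 1).
#' @return An [AssemblyScenario-class].
#' @examples
#' assemblyScenario()
#' @export
assemblyScenario <- function(nGroups = 5L,
                             envGradient = seq(0, 1, length.out = nGroups),
                             fractions = list(
                               aboveground = list(
                                 gamma = 23L, samplesPerGroup = c(8L, 8L, 8L, 8L, 7L),
                                 richnessMean = 11, meanAbundance = 230,
                                 filteringStrength = 4, nicheBreadth = 0.25),
                               belowground = list(
                                 gamma = 20L, samplesPerGroup = rep(6L, 5L),
                                 richnessMean = 5, meanAbundance = 60,
                                 filteringStrength = 0, nicheBreadth = 0.25)),
                             sharedSpecies = 4L,
                             abundanceShape = 1,
                             nEnvNoise = 4L,
                             seed = 1L) {
  new("AssemblyScenario", nGroups = as.integer(nGroups),
      envGradient = as.numeric(envGradient), fractions = fractions,
      sharedSpecies = as.integer(sharedSpecies),
      abundanceShape = as.numeric(abundanceShape),
      nEnvNoise = as.integer(nEnvNoise), seed = as.integer(seed))
}

#' Generate a regional species pool
#'
#' Relative abundances are drawn from a lognormal species-abundance
#' distribution (the standard shape for arthropod assemblages) and
#' normalized to sum to 1; niche optima are uniform on the \[0, 1\]
#' environment axis.
#'
#' @param gamma pool size (>= 1).
#' @param abundanceShape sdlog of the lognormal.
#' @param seed integer seed; NULL uses the current RNG stream.
#' @param speciesNames optional species labels (default sp01, sp02, ...).
#' @return list with `abundance` (named, sums to 1), `optima` (named, in
#'   \[0, 1\]) and `species`.
#' @export
generateRegionalPool <- function(gamma, abundanceShape = 1, seed = NULL,
                                 speciesNames = NULL) {
  if (gamma < 1) stop("gamma must be >= 1")
  if (is.null(speciesNames))
    speciesNames <- sprintf("sp%02d", seq_len(gamma))
  .withSeed(seed, {
    ab <- rlnorm(gamma, meanlog = 0, sdlog = abundanceShape)
    ab <- ab / sum(ab)
    opt <- runif(gamma)
    list(abundance = setNames(ab, speciesNames),
         optima = setNames(opt, speciesNames),
         species = speciesNames)
  })
}

# shared assembly core: membership by weighted draws without replacement,
# abundances multinomial around the pool profile with every member >= 1
.assemble <- function(pool, nSamples, richnessMean, meanAbundance, weights,
                      sampleNames = NULL) {
  gamma <- length(pool$abundance)
  if (richnessMean > gamma) stop("mean richness exceeds pool size")
  if (is.null(sampleNames)) sampleNames <- sprintf("s%02d", seq_len(nSamples))
  k <- pmin(pmax(rpois(nSamples, richnessMean), 1L), gamma)
  m <- matrix(0, nSamples, gamma,
              dimnames = list(sampleNames, pool$species))
  for (i in seq_len(nSamples)) {
    members <- sample.int(gamma, k[i], prob = weights)
    total <- max(k[i], rpois(1L, meanAbundance))
    extra <- stats::rmultinom(1L, total - k[i],
                              prob = pool$abundance[members])[, 1L]
    m[i, members] <- 1 + extra
  }
  CommunityMatrix(m)
}

#' Assemble samples neutrally from a regional pool
#'
#' Each sample's richness is Poisson around `richnessMean` (truncated to
#' \[1, gamma\]); members are drawn without replacement with probability
#' proportional to the pool's relative abundance, irrespective of niche
#' optima; member abundances follow the pool's abundance profile.
#'
#' @param pool a pool from [generateRegionalPool()].
#' @param nSamples number of samples.
#' @param richnessMean expected species per sample.
#' @param meanAbundance expected individuals per sample.
#' @param seed integer seed; NULL uses the current stream.
#' @param sampleNames optional sample labels.
#' @return A [CommunityMatrix-class] of counts.
#' @seealso [assembleFiltered()]
#' @export
assembleNeutral <- function(pool, nSamples, richnessMean,
                            meanAbundance = 100, seed = NULL,
                            sampleNames = NULL) {
  .withSeed(seed, .assemble(pool, nSamples, richnessMean, meanAbundance,
                            weights = pool$abundance,
                            sampleNames = sampleNames))
}

#' Assemble samples under environmental filtering
#'
#' As [assembleNeutral()], but the selection weight of species i is
#' pool_abundance_i * exp(-filteringStrength * (optimum_i - envValue)^2 /
#' (2 * nicheBreadth^2)): species whose niche optima match the local
#' environment are favoured, the more strongly the larger
#' `filteringStrength`. `filteringStrength = 0` reduces exactly to the
#' neutral assembler (same seed, same output).
#'
#' @inheritParams assembleNeutral
#' @param envValue local environment on the niche axis.
#' @param filteringStrength non-negative filtering strength; 0 is neutral.
#' @param nicheBreadth positive width of the Gaussian niche.
#' @return A [CommunityMatrix-class] of counts.
#' @export
assembleFiltered <- function(pool, nSamples, richnessMean, envValue,
                             filteringStrength, nicheBreadth,
                             meanAbundance = 100, seed = NULL,
                             sampleNames = NULL) {
  if (filteringStrength < 0) stop("filteringStrength must be >= 0")
  if (nicheBreadth <= 0) stop("nicheBreadth must be > 0")
  w <- pool$abundance *
    exp(-filteringStrength * (pool$optima - envValue)^2 / (2 * nicheBreadth^2))
  .withSeed(seed, .assemble(pool, nSamples, richnessMean, meanAbundance,
                            weights = w, sampleNames = sampleNames))
}

#' Generate a full synthetic chronosequence dataset
#'
#' Builds the regional pools (with the configured species overlap between
#' two fractions), assembles every group of every fraction under its
#' regime (neutral when `filteringStrength` is 0, filtered otherwise) at
#' that group's environmental value, and assembles the environment table:
#' the gradient itself plus covariates correlated with it (emulating soil
#' chemistry and vegetation responding to disturbance) and uninformative
#' noise variables. Fully reproducible from the scenario seed.
#'
#' @param scenario an [AssemblyScenario-class].
#' @return A [SyntheticDataset-class]; the community metadata carries
#'   `group` and `fraction` columns, and `truth()` records pools and
#'   per-fraction regimes.
#' @examples
#' ds <- generateChronosequenceDataset(assemblyScenario(seed = 11))
#' community(ds)
#' @export
generateChronosequenceDataset <- function(scenario) {
  validObject(scenario)
  .withSeed(scenario@seed, {
    fr <- scenario@fractions
    nFr <- length(fr)
    gammas <- vapply(fr, function(f) as.integer(f$gamma), integer(1))
    shared <- if (nFr == 2L) scenario@sharedSpecies else 0L
    totalSpecies <- sum(gammas) - shared * max(0L, nFr - 1L)
    globalPool <- generateRegionalPool(totalSpecies, scenario@abundanceShape)
    # fraction i's pool is a contiguous slice; consecutive slices overlap
    # by `shared` species
    idx <- list()
    start <- 1L
    for (i in seq_len(nFr)) {
      idx[[i]] <- seq.int(start, start + gammas[i] - 1L)
      start <- start + gammas[i] - shared
    }
    names(idx) <- names(fr)

    groupLabels <- paste0("year", seq_len(scenario@nGroups) - 1L)
    countsList <- list()
    mdList <- list()
    for (i in seq_len(nFr)) {
      nm <- names(fr)[i]
      f <- fr[[i]]
      pool <- list(abundance = globalPool$abundance[idx[[i]]] /
                     sum(globalPool$abundance[idx[[i]]]),
                   optima = globalPool$optima[idx[[i]]],
                   species = globalPool$species[idx[[i]]])
      for (y in seq_len(scenario@nGroups)) {
        ns <- f$samplesPerGroup[y]
        labels <- sprintf("%s_%s_t%02d", substr(nm, 1, 2), groupLabels[y],
                          seq_len(ns))
        cmY <- assembleFiltered(pool, ns, f$richnessMean,
                                envValue = scenario@envGradient[y],
                                filteringStrength = f$filteringStrength,
                                nicheBreadth = f$nicheBreadth,
                                meanAbundance = f$meanAbundance,
                                sampleNames = labels)
        full <- matrix(0, ns, totalSpecies,
                       dimnames = list(labels, globalPool$species))
        full[, idx[[i]]] <- counts(cmY)
        countsList[[length(countsList) + 1L]] <- full
        mdList[[length(mdList) + 1L]] <- data.frame(
          group = rep(groupLabels[y], ns), fraction = rep(nm, ns),
          row.names = labels, stringsAsFactors = FALSE)
      }
    }
    allCounts <- do.call(rbind, countsList)
    allMd <- do.call(rbind, mdList)
    cm <- CommunityMatrix(allCounts, allMd)

    # environment: measured gradient with sample-level noise, covariates
    # tracking the gradient (disturbance-responsive soil/vegetation
    # properties), and pure-noise variables
    grp <- match(allMd$group, groupLabels)
    envTrue <- scenario@envGradient[grp]
    nS <- nrow(allCounts)
    env <- cbind(
      env_gradient = envTrue + rnorm(nS, 0, 0.05),
      soil_moisture = 1.5 * envTrue + rnorm(nS, 0, 0.4),
      soil_ph = -1.0 * envTrue + rnorm(nS, 0, 0.4),
      veg_richness = 3.0 * envTrue + rnorm(nS, 0, 1.0))
    if (scenario@nEnvNoise > 0) {
      noise <- matrix(rnorm(nS * scenario@nEnvNoise), nS)
      colnames(noise) <- sprintf("noise%02d", seq_len(scenario@nEnvNoise))
      env <- cbind(env, noise)
    }
    rownames(env) <- rownames(allCounts)

    truth <- list(
      nGroups = scenario@nGroups,
      envGradient = scenario@envGradient,
      sharedSpecies = shared,
      abundanceShape = scenario@abundanceShape,
      seed = scenario@seed,
      fractions = lapply(fr, function(f)
        f[c("gamma", "samplesPerGroup", "richnessMean", "meanAbundance",
            "filteringStrength", "nicheBreadth")]),
      poolIndices = idx,
      pool = globalPool)
    new("SyntheticDataset", community = cm,
        environment = EnvironmentTable(env), truth = truth)
  })
}

#' Read / write an AssemblyScenario as a YAML config file
#'
#' @param scenario an [AssemblyScenario-class].
#' @param path YAML file path.
#' @return `writeAssemblyScenario` returns `path` invisibly;
#'   `readAssemblyScenario` an [AssemblyScenario-class].
#' @export
writeAssemblyScenario <- function(scenario, path) {
  yaml::write_yaml(list(
    nGroups = scenario@nGroups,
    envGradient = scenario@envGradient,
    fractions = scenario@fractions,
    sharedSpecies = scenario@sharedSpecies,
    abundanceShape = scenario@abundanceShape,
    nEnvNoise = scenario@nEnvNoise,
    seed = scenario@seed), path)
  invisible(path)
}

#' @rdname writeAssemblyScenario
#' @export
readAssemblyScenario <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(assemblyScenario, x)
}
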