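---
title: "Inferring stochastic versus deterministic community assembly with null-model beta-diversity"
author: "betanull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring stochastic versus deterministic community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betanull)
```

## The inference problem

Two families of processes shape which species co-occur in a local sample.
Deterministic (niche-based) processes — environmental filtering, biotic
interactions — select species whose traits match local conditions, so
samples under similar conditions converge on similar compositions.
Stochastic processes — random dispersal, drift, priority effects — produce
compositions that look like random draws from the regional species pool.
Raw beta-diversity cannot separate the two, because the expected
dissimilarity between two samples also depends on how many species each
sample holds (alpha) and how large the pool is (gamma): species-poor
samples from a small pool look similar by force, not by filtering.

The null-deviation approach removes that dependence. For a group of
samples (here: one chronosequence year of one community fraction):

1. measure observed beta-diversity, `beta_obs`, as the mean pairwise
   Sorensen–Czekanowski binary dissimilarity among the group's samples;
2. build many randomized assemblages in which every sample keeps exactly
   its observed species richness and species are drawn from the regional
   pool without replacement, with selection probability proportional to
   each species' regional occurrence frequency;
3. summarize those randomizations by `beta_null`, the mean of the
   randomized beta-diversities, and report the null deviation

   ND = (beta_obs − beta_null) / beta_null.

ND near 0 means the observed turnover is indistinguishable from random
assembly out of the pool (stochastic); values pushing toward ±1 mean the
samples are far more similar (negative) or more different (positive) than
random draws, implicating deterministic structure. Because every
randomized sample keeps its alpha and the pool keeps its gamma, the index
isolates membership structure from richness gradients.

`nullDeviationGroup()` implements steps 1–3; `replicateNullDeviation()`
repeats the estimate with independent seeds (replicate *r* uses
`seed + r`), giving the replicate values that the label-shuffling contrast
test consumes.

## The surrounding workflow

`runAnalysis()` chains the full analysis the way a field study would:

* temporal pooling: repeated collections of the same unit (e.g. June and
  August samples of one focal tree) are summed into one grand sample
  (`binTemporalReplicates()`), because the question is variation among
  years, not within a season;
* community structure: one-way PERMANOVA among groups on Bray–Curtis
  distances of log10(x+1)-transformed, maximum-relativized abundances
  (`logRelativize()`, `permanovaOneWay()`), with pairwise PERMANOVA run
  only when the one-way p-value is below 0.05;
* assembly inference: replicate null deviations per group and fraction,
  then a two-sided permutation test per group contrasting the fractions'
  replicate ND values (`twoGroupPermutationTest()`);
* environment association: Mantel tests of community Sorensen distances
  against Euclidean distances of z-standardized environmental variables,
  plus per-variable partial Mantel tests controlling the remaining
  variables (`mantelTest()`, `partialMantelTest()`).

## Permutation conventions

All label-shuffling tests share the same machinery and conventions:

* When the number of distinct label arrangements is no larger than the
  requested permutation count, every arrangement is enumerated and the
  p-value is the exact fraction of arrangements at least as extreme as
  the observed statistic (the identity arrangement counts, so p is never
  0). `twoGroupPermutationTest()` enumerates label splits,
  `permanovaOneWay()` distinct group assignments, and the Mantel tests
  all N! sample relabelings.
* Otherwise the test samples arrangements uniformly and applies the
  add-one convention p = (k + 1) / (n + 1).
* The ND contrast is two-sided on the absolute mean difference (the
  hypothesis is equality of means); PERMANOVA and Mantel are one-sided
  upper, since only large pseudo-F or r indicates effect.
* Mantel permutes the rows and columns of the second matrix jointly;
  the partial Mantel residualizes both triangles on the control matrix
  by simple linear fits and permutes the residual matrix of the second
  (method of residuals).
* Default 9999 permutations; PERMANOVA on Euclidean distances of
  univariate data reproduces the classical one-way ANOVA F exactly,
  which the test suite asserts.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nRandomizations` | 10000 | randomized assemblage sets per ND estimate |
| `weighting` | occurrence frequency | species-selection weights of the null model; `equiprobable` available |
| `nReplicates` | 5 | independent ND simulations per group |
| `nPermutations` | 9999 | permutations for all label-shuffling tests |
| `base` (`logRelativize`) | 10 | log base of the abundance transform |
| `nOrderings` (`speciesAccumulation`) | 1000 | sample orderings averaged into the accumulation curve |

Choices that were genuinely open, and how they were fixed:

* **Transform order.** The abundance transform is log first, then
  relativization of each species column by its maximum transformed value;
  a `global` flag relativizes by the single overall maximum instead. The
  log base only rescales the relativized values' ordering, so base 10 is
  kept as the conventional choice.
* **Aggregation level of ND.** The headline statistic is group-level
  (mean pairwise dissimilarity within year × fraction), matching one
  plotted value per year and fraction; `sampleMeanDissimilarity()` emits
  the per-sample mean-dissimilarity-to-groupmates diagnostic alongside.
* **beta_null summary.** The mean (not the median) of the randomized
  beta values; the standard deviation is retained in every result for
  Monte-Carlo error assessment.
* **Degenerate inputs.** Empty (all-zero) samples are retained on load
  but rejected by every dissimilarity computation by name: silently
  treating two empty samples as identical would corrupt beta_null. A
  pool that every sample saturates makes beta_null 0 and raises an
  explicit degenerate-null error rather than returning ±Inf.
* **Known versus estimated pools.** By default the regional pool and the
  occurrence weights are estimated from the analysed matrix itself. When
  the pool is known a priori — as in simulation studies — it can be
  passed via the `weights` argument. The distinction matters: evaluating
  ND on data generated by the null model while re-estimating the pool
  from each generated dataset is slightly conservative-positive (species
  absent by chance shrink the fitted pool, and weight noise tightens the
  fitted null), whereas with the known weights the ND distribution is
  centred on zero. The test suite demonstrates both.

## The synthetic assembly simulator

No arthropod count data are deposited for the study design this package
mirrors, so `generateChronosequenceDataset()` produces datasets with the
same shape and known ground truth. The default `assemblyScenario()`
emulates the field design: 5 chronosequence years; an "aboveground"
fraction with a 23-species pool, ~11 species and ~230 individuals per
sample, 8 samples per year (7 in the last); a "belowground" fraction with
a 20-species pool, ~5 species and ~60 individuals per sample, 6 samples
per year; 4 species shared between the pools (69 samples, 39 species,
~10.8k individuals in total). Regional relative abundances follow a
lognormal species-abundance distribution (sdlog 1), the standard shape
for arthropod assemblages; niche optima are uniform on a [0, 1]
environment axis, and the chronosequence years sit on an even gradient
along that axis.

Assembly of one sample: richness is Poisson around the fraction's mean
(truncated to [1, gamma]); members are drawn without replacement with
weight

    abundance_i × exp(−filteringStrength · (optimum_i − env)² / (2 · nicheBreadth²)),

so `filteringStrength = 0` is exactly neutral (identical draws under the
same seed) and large values force co-occurring samples toward the same
best-matching species set. Counts are multinomial around the pool's
abundance profile with every member at least 1. The default regimes give
the aboveground fraction strength 4 with niche breadth 0.25 — strong
enough that its |ND| clearly separates from the neutral fraction while
beta_obs stays well away from 0 — and the belowground fraction strength
0. The environment table carries the measured gradient plus covariates
that track it (emulating disturbance-responsive soil moisture, pH and
vegetation richness) and pure-noise variables.

What the simulator does *not* emulate — and therefore what passing tests
cannot certify about field data: spatial autocorrelation and dispersal
limitation between neighbouring samples, temporal autocorrelation beyond
the year-level gradient, abundance-dependent detection, taxonomic
misassignment, and filtering acting on abundances conditional on
membership. Recovery results on this generator show the estimator chain
is correct, not that any particular field system is deterministic.

## Numerical and scale choices

Null-model randomization represents assemblages as 0/1 matrices and
computes mean pairwise Sorensen through one cross-product per draw, so a
10,000-draw estimate for an 8-sample group runs in about a second.
Weighted sampling without replacement uses sequential draws with
renormalized weights (base R `sample()` semantics), which is also the
reference distribution the enumeration oracle in the tests defines. The
validation suite scales its simulations to stay quick while keeping
Monte-Carlo error in check: the enumeration cross-check uses a 3-sample,
4-species instance (216 enumerable assemblage triples) against 10,000
draws; the centering experiment uses 200 self-generated datasets at 500
randomizations; the recovery experiment 50 scenario replicates at 150
randomizations and the strength sweep {0, 1, 4} at 8 replicates each;
test calibration uses 1000 null datasets at 99 permutations. All
randomized procedures take explicit integer seeds and restore the
caller's RNG state, so every reported number is bit-reproducible from
its seed, and `runAnalysis()` records the master seed and derived
settings in a machine-readable manifest.

## Known limitations

* The null model is binary (membership-based). Abundance-weighted null
  models (e.g. individual-based Raup–Crick variants) are out of scope.
* ND magnitudes are comparable across groups only at similar alpha and
  gamma; comparing fractions with very different richness regimes leans
  on the null model's alpha/gamma conditioning being adequate.
* The pairwise PERMANOVA applies no multiplicity correction by default
  (Holm is available), mirroring common field practice; interpret
  pairwise p-values accordingly.
* Mantel tests have known low power against nonlinear distance
  relationships; the partial Mantel controls one matrix linearly.
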