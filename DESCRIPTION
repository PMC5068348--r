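Package: betanull
Title: Null-Model Beta-Diversity and Community Assembly Inference
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the relative influence of stochastic versus deterministic
    processes on community assembly from site-by-species matrices. Implements
    the null-deviation statistic (the relative difference between observed
    beta-diversity and the beta-diversity of communities randomly assembled
    from the regional species pool), replicate null-deviation simulations with
    label-shuffling permutation tests, one-way and pairwise PERMANOVA on
    dissimilarity matrices, and Mantel and partial Mantel tests against
    environmental distance matrices. Includes a chronosequence-structured
    community simulator with tunable environmental filtering for validating
    the full inference pipeline against known assembly regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    BiocGenerics,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
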