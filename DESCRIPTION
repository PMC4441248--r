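Package: msydemog
Title: Coalescent Demographic Inference and Diversity Statistics for
    Y-Chromosome Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-locus demographic inference for non-recombining haploid
    data such as the male-specific region of the Y chromosome (MSY).
    Provides a coalescent simulator under five piecewise demographic models
    with uniform priors, finite-sites mutation, derived site frequency
    spectrum summaries, approximate Bayesian computation (rejection,
    logistic-regression model choice, local-linear regression adjustment
    with a logtan transform), intrapopulation diversity statistics
    (segregating sites, singletons, Tajima's D, Fu's FS) with coalescent
    null distributions, geographic cline correlation tests, and
    rho-statistic TMRCA dating of clades on mutation-count trees.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    nnet,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
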