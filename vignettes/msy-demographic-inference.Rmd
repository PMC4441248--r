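---
title: "Demographic inference for a single haploid locus: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference for a single haploid locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msydemog)
```

## The inference problem

The male-specific region of the Y chromosome (MSY) is inherited as a
single non-recombining haploid locus, so an entire resequenced region —
here 3,724,156 bp — carries one genealogy per population sample.  That
makes it a sensitive, if noisy, recorder of male demographic history:
population expansions produce star-like genealogies with an excess of
rare variants, bottlenecks the opposite.  This package implements the
full inferential chain for such data: coalescent simulation under
competing demographic models, summary through the derived site frequency
spectrum (SFS), approximate Bayesian computation (ABC) for model choice
and parameter estimation, classical diversity statistics with coalescent
null distributions, and rho-statistic dating of clades in the underlying
phylogeny.

## The five demographic models

All models describe one population of haploid effective size `N(t)`,
with time `t` in generations before the present and a generation time of
30 years.

* **M1** — constant size `N` (uniform prior 20–20,000).
* **M2** — bottleneck: ancient constant size `NA` (1,001–20,000), an
  exponential reduction spanning `LEX` generations (5–634), then a small
  constant size `NBOT` (20–1,000) for the last `T2` generations (0–30).
* **M3** — as M2, but the reduction (to `NER`, 20–1,000) is followed by
  an exponential re-expansion over the last `T2` generations up to the
  current size `NC` (1,001–20,000).
* **M4** — the mirror of M2: an expansion from a small ancient size `NA`
  (20–1,000) to a large current size `NC` (1,001–20,000).
* **M5** — the mirror of M3: an expansion to `NEE` (1,001–20,000)
  followed by a reduction to `NC` (20–1,000).

The onset of the oldest change is `T1 = T2 + LEX`, never sampled
independently: with the stated `LEX` and `T2` priors, `T1` cannot exceed
664 generations, respecting the Last Glacial Maximum (about 20,000
years, i.e. 666.7 generations) as the upper bound for the first
demographic change.  The ancient-size priors of M3 and M5 are not
spelled out in the source description of the models; we set them by
symmetry (M3 like M2, M5 like M4), which is the only assignment that
makes each pair "the same parameterization with the direction of change
reversed".

"Exponential" change interpolates log-linearly in size between the
epoch's endpoint sizes — the standard reading of an exponential
reduction or expansion between two fixed sizes.  Sizes are haploid
(male) effective numbers throughout; because the locus is haploid, no
ploidy scaling is applied anywhere.

The per-site per-generation mutation rate is drawn once per replicate
from a Normal prior with mean 3.01e-8, truncated at zero.  The source
states the mean and a 95% CI of 2.77–3.26e-8; we recover the sd as the
CI half-width divided by 1.96, giving 1.25e-9.

## Coalescent simulation

With `k` lineages at time `t` the pair-coalescence intensity is
`k(k-1)/2 / N(t)`.  Waiting times are simulated by time rescaling in
continuous time: a unit exponential deviate is inverted through the
cumulative hazard, which is closed-form inside constant and exponential
epochs; hazard not consumed within an epoch is carried across the
boundary (inverse-CDF per epoch, no discretization).  The tests verify
the analytic expectations `E[pairwise coalescence] = N` and
`E[TMRCA] = 2N(1 - 1/n)` and, for distributional correctness, compare
TMRCA samples against two independent oracle simulators (plain
exponential waits for constant `N`; numerical hazard inversion by
`integrate()` + `uniroot()` for exponential growth) with
Kolmogorov–Smirnov tests at alpha = 0.01.

Mutation is finite-sites with four states and no
transition/transversion bias: the number of hits is Poisson with mean
`mu * L * total branch length`, each hit lands on a branch with
probability proportional to its length and at a position uniform on
`1..L`, and replaces the current base with one of the other three
uniformly.  Repeat hits at one position are applied in age order along
lineages, so a site can partially revert (fewer derived carriers) or
become triallelic.  Sites that revert in every tip are dropped;
triallelic sites are excluded from the SFS, which requires a single
derived allele.  At the study's rates the expected triallelic fraction
is negligible, which the simulated tables confirm.

## Summaries and ABC

Data are summarized by the derived SFS `xi_1..xi_{n-1}`.  Following the
source protocol, only categories with at least one observed polymorphic
site enter the comparison; each retained category is scaled by its
median absolute deviation across the reference table (MAD is the
convention of the ABC toolchain this machinery mirrors; the source does
not state its scaling).  Zero-MAD categories are scaled by 1.

Model choice fits a multinomial logistic regression of the model label
on the scaled summaries over the nearest rows (default 1% of the table,
mirroring the 10,000-of-1,000,000 acceptance rule of the full-size
analysis), evaluated at the observation; a small ridge penalty
stabilizes the fit under separation, and the rejection-count posterior
is always available as a cross-check.  Parameter estimation follows the
local-linear regression-adjustment recipe: parameters are mapped to the
real line by the monotone *logtan* transform
`y = ln(tan(pi/2 * (x - a)/(b - a)))` for a uniform prior on `(a, b)`,
weighted with an Epanechnikov kernel of distance over the rejection
tolerance, regressed on the summaries, and adjusted as
fitted-at-the-observation plus residuals.  Back-transformation
guarantees every adjusted draw lies inside the prior support.  Point
estimates are reported as both the weighted median and the
kernel-density mode (the source does not say which it used), with
equal-tailed 95% credible intervals and a per-parameter weighted `R^2`.
The derived `T1` is recomposed as adjusted `T2 +` adjusted `LEX`, never
regressed directly.  A singular design falls back to the unadjusted
rejection sample with a flag.

Validation harnesses generate pseudo-observed datasets (pods) with
known parameters: `power_analysis()` tabulates how often model choice
recovers the generating model, and `parameter_recovery_suite()` checks
95% credible-interval coverage.  In the packaged test conditions —
a narrow constant-size model against a strong (about 100-fold)
expansion, 2,000 reference simulations per model and 200 pods —
true-positive rates exceed 0.6 for both models and coverage sits inside
the binomial band `[0.88, 0.99]` around the nominal 0.95.  Time
parameters remain weakly identified: the `T1` posterior keeps more than
half the prior interval width, the expected behaviour for a
single-locus SFS.

## Diversity statistics

`segregating_sites()` counts sites with at least two distinct
non-missing alleles.  The singleton summary is deliberately
*per-individual*: a singleton site carries a minor allele in exactly one
individual, each individual's count is the number of singleton sites it
carries, and the median and sd are taken across individuals.  This is
the only reading consistent with half-integer medians at n = 20 and
with sd values exceeding the median in the tabulated cohort data, and
is recorded here as an interpretation.  Missing calls are handled
pairwise-complete without rescaling — the simplest defensible treatment
for data that are ~99.8% complete.

Tajima's `D` uses the 1989 variance constants; Fu's `FS` takes
`theta = pi` (mean pairwise differences) and computes
`S' = P(K >= k_obs)` under the Ewens sampling formula, with unsigned
Stirling numbers of the first kind evaluated in log space by the
`|s(n+1,k)| = n|s(n,k)| + |s(n,k-1)|` recurrence — naive integer
products overflow double precision well before n = 20.  Both statistics
are tested against independent oracles (a separately coded constants
implementation; exact integer Stirling rows; a Chinese-restaurant
Monte-Carlo of the Ewens partition).

P-values for `D` and `FS` come from constant-size neutral coalescent
simulations conditioned on the observed `n` and `S` (fixed-S null,
the default of the software used for the original tables), as the
fraction of simulated values at or below the observed one.  Because the
original p-values came from a specific external implementation with its
own simulation protocol, point statistics rather than p-values are the
quantities to compare across implementations.

Geographic clines are tested with Pearson correlation through
`stats::cor.test()` — statistic, df and two-sided p exactly as in the
original analysis environment.

## Rho dating

For a clade, `rho` is the mean number of mutations from the clade root
to its tips; its standard deviation uses the Saillard branch-weight
formula `sd^2 = sum_b (n_b/n)^2 l_b` (the alternative rho reference
offers no variance estimator, so this one governs).  The scaled rate
converts mutations to years: `1/(mu * L)` with the published per-site
per-year rate gives 268.5 (246.3–291.9) years per mutation over the
3,724,156 bp analysed; reported ages are rounded to the nearest 10
years, half-up at the tens digit — the variant consistent with the
published rounded ages.  Non-integer branch counts (consensus trees)
are accepted with a warning.

## Numerical and degenerate-input choices

* Prior bounds: `uniform_prior()` requires `lower < upper` and
  non-negative bounds (`T2` legitimately starts at 0); degenerate
  point priors are rejected at construction.
* `T2 = 0` collapses the recent constant epoch; the epoch list omits
  zero-width epochs.
* `mu = 0` is rejected (`drop_mutations` requires `mu > 0`); the SFS of
  a replicate with no polymorphic site is the zero vector and such pods
  are skipped by the validation harnesses.
* `logtan` clamps values at machine epsilon inside the bounds with a
  warning instead of returning infinities.
* Rejection ties at the acceptance boundary are broken by row order
  after a seeded shuffle, keeping runs reproducible.
* Every stochastic entry point takes a seed; batch runs split one root
  seed into per-replicate seeds (recorded in the table attributes and
  the run manifest), so any single replicate can be replayed.

## Problem sizes

The packaged analysis scripts and tests run scaled-down configurations
chosen to keep the full workflow in the minutes range on one core while
leaving every Monte-Carlo check adequately powered: 400 reference
simulations per model at the full locus length in the analysis scripts;
2,000–3,000 simulations per model, 200 pods, and 1,000–8,000
replicates per analytic expectation in the tests; toy ABC scenarios use
a 200 kb locus.  All counts are arguments, so the full-size analysis
(10^6 simulations per model, 1,000 pods) is the same code with larger
numbers.

## What the synthetic data do and do not emulate

The generator reproduces the study conditions: a single non-recombining
haploid locus, finite-sites mutation without transition/transversion
bias, piecewise demographies from the stated priors, and per-replicate
mutation-rate draws.  It does not model recombination (correct for the
MSY), migration or population structure, selection, sequencing error,
or missing genotype calls — simulated samples are complete.  Passing
tests therefore demonstrate the correctness of the simulator and
inference machinery under the assumed model class, not robustness of
the demographic conclusions to structure, selection or call errors in
real cohorts.

## Known limitations

* Single-locus data weakly identify time parameters; `T1` intervals are
  expected to remain wide, and model pairs that overlap in SFS space
  (e.g. an expansion followed by a mild reduction versus a pure
  expansion) trade posterior mass.
* The logistic model-choice acceptance fraction (1% default) is an
  inference from the parameter-estimation rule, not a stated value, and
  is configurable.
* Fu's FS haplotype counts treat a missing call as its own symbol when
  collapsing haplotypes; with near-complete data the effect is nil, but
  heavily missing data would need a different treatment.
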