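# Intrapopulation diversity statistics: segregating sites, singleton
# summaries, mean pairwise differences, Tajima's D, Fu's FS, coalescent
# null p-values and geographic cline correlations.

#' Haploid population sample
#'
#' @param alleles Character matrix, sites x individuals; `NA` marks a
#'   missing call.
#' @param pop_id Population identifier.
#' @param positions Optional site positions (defaults to row index).
#' @param individuals Optional individual ids (defaults to column names).
#' @return Object of class `population_sample`.
#' @export
population_sample <- function(alleles, pop_id = "pop",
                              positions = NULL, individuals = NULL) {
  if (!is.matrix(alleles)) alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "character"
  individuals <- individuals %||% colnames(alleles) %||%
    paste0("ind", seq_len(ncol(alleles)))
  positions <- positions %||% seq_len(nrow(alleles))
  stopifnot(length(individuals) == ncol(alleles),
            length(positions) == nrow(alleles))
  colnames(alleles) <- individuals
  structure(list(pop_id = pop_id, individuals = individuals,
                 positions = positions, alleles = alleles),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("Population sample '%s': %d individuals, %d sites\n",
              x$pop_id, length(x$individuals), length(x$positions)))
  invisible(x)
}

#' Number of segregating (polymorphic) sites
#'
#' A site is polymorphic when at least two distinct alleles are observed
#' among its non-missing calls.
#' @param sample A [population_sample()].
#' @return Integer count.
#' @export
segregating_sites <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  a <- sample$alleles
  if (nrow(a) == 0) return(0L)
  n_called <- rowSums(!is.na(a))
  if (any(n_called == 0)) stop("site with all calls missing")
  poly <- apply(a, 1, function(row) {
    length(unique(row[!is.na(row)])) >= 2L
  })
  sum(poly)
}

#' Singleton summary per individual
#'
#' A singleton site carries a minor allele in exactly one individual.  Each
#' individual's count is the number of singleton sites for which it is the
#' carrier; the summary reports the median and (sample) standard deviation
#' of these counts across individuals, which is why medians can be
#' half-integers at even sample sizes.
#'
#' @param sample A [population_sample()].
#' @return List: `per_individual_counts` (named), `median`, `sd`.
#' @export
singleton_summary <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  a <- sample$alleles
  counts <- stats::setNames(integer(ncol(a)), sample$individuals)
  for (s in seq_len(nrow(a))) {
    row <- a[s, ]
    tab <- table(row[!is.na(row)])
    if (length(tab) < 2L) next
    ones <- names(tab)[tab == 1L]
    if (length(ones) != 1L) next   # need exactly one count-1 allele
    carrier <- which(row == ones)
    counts[carrier] <- counts[carrier] + 1L
  }
  list(per_individual_counts = counts,
       median = stats::median(as.numeric(counts)),
       sd = if (length(counts) > 1) stats::sd(counts) else 0)
}

#' Mean number of pairwise differences (pi)
#'
#' Average count of differing sites over all n(n-1)/2 haplotype pairs,
#' comparing only sites where both members of a pair are called.
#' @param sample A [population_sample()].
#' @return Numeric (sites).
#' @export
mean_pairwise_differences <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  a <- sample$alleles
  n <- ncol(a)
  if (n < 2) stop("need at least 2 individuals for pi")
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      both <- !is.na(a[, i]) & !is.na(a[, j])
      total <- total + sum(a[both, i] != a[both, j])
    }
  }
  total / (n * (n - 1) / 2)
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-diversity and
#' segregating-sites estimators of theta, with the Tajima (1989) variance
#' constants.
#'
#' @param S Number of segregating sites (>= 1).
#' @param pi Mean pairwise differences.
#' @param n Sample size (>= 4).
#' @return Numeric; `NA` with a warning when not computable.
#' @export
tajimas_d <- function(S, pi, n) {
  if (n < 4) stop("Tajima's D requires n >= 4")
  if (S < 1) {
    warning("Tajima's D undefined at S = 0")
    return(NA_real_)
  }
  a1 <- harmonic_sum(n - 1)
  a2 <- harmonic_sum(n - 1, power = 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Log unsigned Stirling numbers of the first kind
#'
#' Row `n` of |s(n, k)| for k = 1..n, computed in log space with the
#' recurrence |s(n+1,k)| = n |s(n,k)| + |s(n,k-1)| (log-sum-exp form);
#' naive products overflow well before n = 20.
#' @noRd
log_stirling_row <- function(n) {
  row <- c(0)  # |s(1,1)| = 1
  if (n == 1) return(row)
  for (m in seq_len(n - 1)) {
    new <- numeric(m + 1)
    for (k in seq_len(m + 1)) {
      terms <- c(if (k <= m) log(m) + row[k] else NULL,
                 if (k >= 2) row[k - 1] else NULL)
      new[k] <- logsumexp(terms)
    }
    row <- new
  }
  row
}

#' Ewens distribution of the number of distinct haplotypes
#'
#' P(K = k) for a sample of n under the Ewens sampling formula with scaled
#' mutation parameter theta.
#' @param n Sample size.
#' @param theta Scaled mutation parameter (> 0).
#' @return Numeric vector of length n (k = 1..n).
#' @export
ewens_k_distribution <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  ls <- log_stirling_row(n)
  logp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(logp)
}

#' Fu's FS
#'
#' `S' = P(K >= k_obs | theta = pi)` under the Ewens sampling formula;
#' `FS = ln(S' / (1 - S'))`.  Strongly negative values indicate an excess
#' of haplotypes relative to pairwise diversity, as after an expansion.
#'
#' @param pi Mean pairwise differences (> 0), used as theta.
#' @param n Sample size.
#' @param k_obs Observed number of distinct haplotypes (1..n).
#' @return Numeric; `NA` with a warning when the statistic degenerates
#'   (`pi = 0` or `k_obs = 1`, where S' = 1).
#' @export
fus_fs <- function(pi, n, k_obs) {
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n)
  if (is.na(pi) || pi <= 0) {
    warning("Fu's FS undefined at pi = 0")
    return(NA_real_)
  }
  if (k_obs == 1) {
    warning("Fu's FS undefined at k_obs = 1 (S' = 1)")
    return(NA_real_)
  }
  ls <- log_stirling_row(n)
  logp <- ls + seq_len(n) * log(pi) - sum(log(pi + 0:(n - 1)))
  log_s_hi <- logsumexp(logp[k_obs:n])
  log_s_lo <- logsumexp(logp[seq_len(k_obs - 1)])
  log_s_hi - log_s_lo
}

#' Number of distinct haplotypes
#'
#' Individuals with identical call vectors (missing compared as its own
#' symbol) collapse to one haplotype.
#' @param sample A [population_sample()].
#' @export
distinct_haplotypes <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  keys <- apply(sample$alleles, 2, paste, collapse = "\r")
  length(unique(keys))
}

#' Simulate the fixed-S neutral null for D and FS
#'
#' Constant-size coalescent genealogies with exactly `S` infinite-sites
#' mutations placed proportionally to branch length; returns simulated D
#' and FS values.
#' @noRd
simulate_neutral_null <- function(n, S, n_sims, seed = NULL) {
  maybe_set_seed(seed)
  demo <- build_demography(list(model_id = "M1", values = c(N = 1000)))
  d_sim <- numeric(n_sims)
  fs_sim <- numeric(n_sims)
  npairs <- n * (n - 1) / 2
  for (r in seq_len(n_sims)) {
    g <- coalescent_sim(demo, n)
    br <- genealogy_branches(g)
    tb <- genealogy_tips_below(g)
    mut_branch <- sample.int(nrow(br), S, replace = TRUE, prob = br$length)
    nb <- lengths(tb)[br$node[mut_branch]]
    pi_sim <- sum(nb * (n - nb)) / npairs
    # haplotype identity: tips separated by no mutated branch are identical
    carrier <- matrix(FALSE, n, length(unique(mut_branch)))
    for (jj in seq_along(unique(mut_branch))) {
      carrier[tb[[br$node[unique(mut_branch)[jj]]]], jj] <- TRUE
    }
    k_sim <- nrow(unique(carrier))
    d_sim[r] <- tajimas_d(S, pi_sim, n)
    fs_sim[r] <- if (k_sim > 1) fus_fs(pi_sim, n, k_sim) else NA_real_
  }
  list(d = d_sim, fs = fs_sim)
}

#' Coalescent p-values for Tajima's D and Fu's FS
#'
#' Simulates constant-size neutral genealogies conditioned on the observed
#' sample size and number of segregating sites (fixed-S null) and reports
#' the lower-tail probabilities `P(D_sim <= D_obs)` and
#' `P(FS_sim <= FS_obs)`.
#'
#' @param sample A [population_sample()], or `NULL` when `S`, `d_obs`,
#'   `fs_obs` and `n` are given directly.
#' @param n_sims Number of null simulations.
#' @param seed Integer seed.
#' @param S,d_obs,fs_obs,n Direct inputs overriding `sample`.
#' @return List: `p_d`, `p_fs`, `n_sims`.
#' @export
diversity_significance <- function(sample = NULL, n_sims = 1000, seed = NULL,
                                   S = NULL, d_obs = NULL, fs_obs = NULL,
                                   n = NULL) {
  if (!is.null(sample)) {
    stopifnot(inherits(sample, "population_sample"))
    n <- length(sample$individuals)
    S <- segregating_sites(sample)
    pi <- mean_pairwise_differences(sample)
    d_obs <- tajimas_d(S, pi, n)
    fs_obs <- fus_fs(pi, n, distinct_haplotypes(sample))
  }
  stopifnot(!is.null(S), !is.null(n), S >= 1)
  null <- simulate_neutral_null(n, S, n_sims, seed)
  list(p_d = mean(null$d <= d_obs, na.rm = TRUE),
       p_fs = if (is.na(fs_obs)) NA_real_ else
         mean(null$fs <= fs_obs, na.rm = TRUE),
       n_sims = n_sims)
}

#' Diversity table across populations
#'
#' One row per population: N, S, the singleton median and sd, Tajima's D
#' and Fu's FS with coalescent p-values.
#'
#' @param samples Named list of [population_sample()] objects.
#' @param n_sims Null simulations per population for the p-values (0 to
#'   skip).
#' @param seed Integer seed.
#' @return data.frame with columns `pop`, `N`, `S`, `median_singletons`,
#'   `sd_singletons`, `D`, `p_D`, `FS`, `p_FS`.
#' @export
diversity_table <- function(samples, n_sims = 1000, seed = 1) {
  seeds <- derive_seeds(seed, length(samples))
  rows <- lapply(seq_along(samples), function(i) {
    smp <- samples[[i]]
    n <- length(smp$individuals)
    S <- segregating_sites(smp)
    sing <- singleton_summary(smp)
    pi <- mean_pairwise_differences(smp)
    D <- if (S >= 1 && n >= 4) tajimas_d(S, pi, n) else NA_real_
    FS <- if (pi > 0) suppressWarnings(fus_fs(pi, n, distinct_haplotypes(smp)))
          else NA_real_
    p_d <- p_fs <- NA_real_
    if (n_sims > 0 && S >= 1) {
      sig <- diversity_significance(S = S, d_obs = D, fs_obs = FS, n = n,
                                    n_sims = n_sims, seed = seeds[i])
      p_d <- sig$p_d
      p_fs <- sig$p_fs
    }
    data.frame(pop = smp$pop_id, N = n, S = S,
               median_singletons = sing$median, sd_singletons = sing$sd,
               D = D, p_D = p_d, FS = FS, p_FS = p_fs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of a diversity measure with a geographic coordinate
#'
#' @param values Per-population statistic (no missing values).
#' @param coordinate Per-population latitude or longitude.
#' @return List: `r`, `t`, `p` (two-sided, t distribution with m - 2 df).
#' @export
correlation_test <- function(values, coordinate) {
  stopifnot(length(values) == length(coordinate))
  if (length(values) < 3) stop("need at least 3 populations")
  if (anyNA(values) || anyNA(coordinate)) stop("missing values not allowed")
  if (stats::var(values) == 0 || stats::var(coordinate) == 0) {
    stop("zero variance in one of the vectors")
  }
  ct <- stats::cor.test(values, coordinate, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       p = ct$p.value)
}
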