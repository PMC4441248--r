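# Diversity statistics: S, singletons, pi, Tajima's D, Fu's FS, null
# p-values, correlations.

toy_sample <- function(cols) {
  population_sample(do.call(cbind, cols))
}

test_that("segregating sites counts polymorphic sites over non-missing calls", {
  s <- toy_sample(list(c("A", "A"), c("A", "G"), c("A", "A")))
  expect_equal(segregating_sites(s), 1)
  mono <- toy_sample(list(c("A", "C"), c("A", "C"), c("A", "C")))
  expect_equal(segregating_sites(mono), 0)
  # a missing call does not make a site polymorphic
  m <- matrix(c("A", "A", NA,
                "A", "G", "G"), nrow = 2, byrow = TRUE)
  expect_equal(segregating_sites(population_sample(m)), 1)
  allmiss <- population_sample(matrix(NA_character_, 1, 3))
  expect_error(segregating_sites(allmiss), "missing")
})

test_that("singleton summary is per individual, explaining half-integer medians", {
  # carriers {ind1}, {ind1}, {ind3} -> counts (2, 0, 1, 0)
  m <- rbind(c("G", "A", "A", "A"),
             c("G", "A", "A", "A"),
             c("A", "A", "T", "A"))
  ss <- singleton_summary(population_sample(m))
  expect_equal(unname(ss$per_individual_counts), c(2L, 0L, 1L, 0L))
  expect_equal(ss$median, 0.5)
  expect_equal(ss$sd, sd(c(2, 0, 1, 0)))
  # no singletons
  none <- population_sample(rbind(c("A", "A", "G", "G")))
  s0 <- singleton_summary(none)
  expect_equal(unname(s0$per_individual_counts), rep(0L, 4))
  expect_equal(s0$median, 0)
  expect_equal(s0$sd, 0)
  # even sample size: median of 10 a's and 10 b's is (a+b)/2
  cnt <- c(rep(3L, 10), rep(8L, 10))
  expect_equal(median(cnt), 5.5)
})

test_that("mean pairwise differences enumerate all haplotype pairs", {
  same <- toy_sample(list(c("A", "C", "T"), c("A", "C", "T")))
  expect_equal(mean_pairwise_differences(same), 0)
  tri <- toy_sample(list(c("A", "A", "T"), c("A", "A", "G"), c("C", "A", "T")))
  expect_equal(mean_pairwise_differences(tri), 4 / 3)
  # 4 copies of one haplotype, 1 differing at one site: pi = 4/10
  five <- toy_sample(c(rep(list(c("A", "A")), 4), list(c("A", "G"))))
  expect_equal(mean_pairwise_differences(five), 4 / 10)
  expect_error(mean_pairwise_differences(toy_sample(list(c("A", "A")))),
               "2 individuals")
})

test_that("Tajima's D matches the independent constants oracle to 1e-10", {
  expect_equal(tajimas_d(16, 16 / sum(1 / 1:9), 10), 0)
  set.seed(55)
  for (r in 1:100) {
    n <- sample(4:40, 1)
    S <- sample(1:200, 1)
    pi <- runif(1, 0, S)
    expect_equal(tajimas_d(S, pi, n), oracle_tajimas_d(S, pi, n),
                 tolerance = 1e-10)
  }
  expect_warning(d0 <- tajimas_d(0, 0, 10), "S = 0")
  expect_true(is.na(d0))
})

test_that("neutral constant-N simulations give Tajima's D near zero", {
  d <- constant_demo(1000)
  set.seed(61)
  vals <- replicate(600, {
    g <- coalescent_sim(d, 20)
    st <- drop_mutations(g, 2e-7, 1e5)
    S <- length(st$positions)
    if (S < 1) return(NA_real_)
    tajimas_d(S, mean_pairwise_differences(population_sample(st$alleles)), 20)
  })
  expect_gt(mean(vals, na.rm = TRUE), -0.25)
  expect_lt(mean(vals, na.rm = TRUE), 0.25)
})

test_that("the Ewens haplotype-count distribution is exact and normalized", {
  # n = 4, theta = 1: |s(4,k)| = (6, 11, 6, 1), denominator 24
  p <- ewens_k_distribution(4, 1)
  expect_equal(p, c(6, 11, 6, 1) / 24, tolerance = 1e-12)
  # against exact integer Stirling numbers at another theta
  th <- 2.5
  ls <- oracle_stirling_row(6)
  denom <- prod(th + 0:5)
  expect_equal(ewens_k_distribution(6, th),
               ls * th^(1:6) / denom, tolerance = 1e-12)
  for (n in c(5, 12, 20, 30)) {
    for (theta in c(0.1, 1, 10)) {
      expect_equal(sum(ewens_k_distribution(n, theta)), 1, tolerance = 1e-12)
    }
  }
})

test_that("Ewens mean haplotype count matches the Chinese-restaurant oracle", {
  n <- 15; theta <- 3
  e_k <- sum(seq_len(n) * ewens_k_distribution(n, theta))
  expect_equal(e_k, sum(theta / (theta + 0:(n - 1))), tolerance = 1e-10)
  set.seed(71)
  ks <- replicate(4000, oracle_crt_k(n, theta))
  expect_lt(abs(mean(ks) - e_k), 3 * sd(ks) / sqrt(length(ks)))
})

test_that("Fu's FS reproduces the exact small-sample case and degenerates cleanly", {
  expect_equal(fus_fs(1, 4, 3), log(7 / 17), tolerance = 1e-12)
  expect_warning(f1 <- fus_fs(1, 4, 1), "k_obs = 1")
  expect_true(is.na(f1))
  expect_warning(f0 <- fus_fs(0, 4, 2), "pi = 0")
  expect_true(is.na(f0))
})

test_that("Fu's FS is negative under expansion and near zero at constant size", {
  set.seed(81)
  run_fs <- function(demo) {
    replicate(300, {
      g <- coalescent_sim(demo, 15)
      st <- drop_mutations(g, 2e-7, 1e5)
      if (length(st$positions) < 1) return(NA_real_)
      smp <- population_sample(st$alleles)
      k <- distinct_haplotypes(smp)
      pi <- mean_pairwise_differences(smp)
      if (pi == 0 || k < 2) return(NA_real_)
      fus_fs(pi, 15, k)
    })
  }
  fs_const <- run_fs(constant_demo(1000))
  expansion <- build_demography(list(
    model_id = "M4", values = c(NA_ = 50, NC = 15000, T2 = 0, LEX = 100)))
  fs_exp <- run_fs(expansion)
  expect_lt(mean(fs_exp, na.rm = TRUE), -1)
  expect_lt(abs(mean(fs_const, na.rm = TRUE)), 1)
  expect_lt(mean(fs_exp, na.rm = TRUE), mean(fs_const, na.rm = TRUE))
})

test_that("coalescent null p-values are calibrated and reproducible", {
  sig1 <- diversity_significance(S = 30, d_obs = 0, fs_obs = 0, n = 15,
                                 n_sims = 400, seed = 5)
  sig2 <- diversity_significance(S = 30, d_obs = 0, fs_obs = 0, n = 15,
                                 n_sims = 400, seed = 5)
  expect_identical(sig1, sig2)
  expect_gte(sig1$p_d, 0); expect_lte(sig1$p_d, 1)
  # D at the null median has p near 0.5; far-left D has p near 0
  expect_gt(sig1$p_d, 0.2); expect_lt(sig1$p_d, 0.8)
  lo <- diversity_significance(S = 30, d_obs = -50, fs_obs = -50, n = 15,
                               n_sims = 400, seed = 6)
  expect_equal(lo$p_d, 0)
  expect_equal(lo$p_fs, 0)
})

test_that("diversity_table has the Table-2 shape", {
  set.seed(91)
  d <- constant_demo(800)
  samples <- lapply(c(a = "a", b = "b"), function(id) {
    g <- coalescent_sim(d, 10)
    st <- drop_mutations(g, 2e-7, 1e5)
    s <- population_sample(st$alleles, pop_id = id)
    s
  })
  tab <- diversity_table(samples, n_sims = 100, seed = 2)
  expect_equal(names(tab), c("pop", "N", "S", "median_singletons",
                             "sd_singletons", "D", "p_D", "FS", "p_FS"))
  expect_equal(tab$N, c(10, 10))
  expect_true(all(tab$S >= 0))
})

test_that("correlation tests reproduce the closed-form Pearson t and p", {
  ct <- correlation_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(ct$r, 0.6, tolerance = 1e-12)
  expect_equal(ct$t, 0.6 * sqrt(2 / (1 - 0.36)), tolerance = 1e-10)
  expect_equal(ct$p, 2 * pt(-abs(ct$t), df = 2), tolerance = 1e-10)
  perfect <- correlation_test(1:5, 2 * (1:5))
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-10)
  expect_error(correlation_test(1:2, 1:2), "3 populations")
  expect_error(correlation_test(rep(1, 4), 1:4), "zero variance")
  expect_error(correlation_test(c(1, NA, 3), 1:3), "missing")
})
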