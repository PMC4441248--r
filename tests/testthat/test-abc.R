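# ABC machinery: summary masking/scaling, rejection, model posteriors,
# logtan transform, regression adjustment, power and coverage harnesses.

make_toy_tables <- function(n_sims = 600, n = 8, seed = 1) {
  list(M1 = simulate_batch(toy_spec_m1(), n_sims, n, seed = seed),
       M4 = simulate_batch(toy_spec_m4(), n_sims, n, seed = seed + 1))
}

test_that("summary masking keeps observed-polymorphic categories only", {
  tab <- simulate_batch(toy_spec_m1(), 50, 4, seed = 9)
  obs <- c(5, 0, 2)
  summ <- build_summary(obs, tab)
  expect_equal(summ$mask, c(1, 3))
  expect_equal(length(summ$observed), 2)
  expect_equal(ncol(summ$summaries), 2)
  # all categories present -> identity mask
  summ2 <- build_summary(c(3, 1, 2), tab)
  expect_equal(summ2$mask, 1:3)
  expect_error(build_summary(c(0, 0, 0), tab), "empty")
})

test_that("rejection keeps the nearest rows and degenerates to the prior", {
  tabs <- make_toy_tables()
  comb <- bind_ref_tables(tabs)
  obs <- as.numeric(tabs$M1[3, grep("^xi_", names(tabs$M1))])
  summ <- build_summary(obs, comb)
  rej <- abc_reject(summ, 10, seed = 1)
  expect_equal(length(rej$index), 10)
  expect_equal(rej$tol, max(rej$dist))
  # a row identical to the observation is accepted at distance 0
  expect_true(any(rej$dist == 0))
  # full acceptance returns the whole table: model posterior = proportions
  rej_all <- abc_reject(summ, nrow(comb))
  p <- model_posterior_rejection(rej_all)
  expect_equal(as.numeric(p), c(0.5, 0.5))
  expect_error(abc_reject(summ, 0), "n_accept")
  expect_error(abc_reject(summ, nrow(comb) + 1), "exceeds")
})

test_that("full-acceptance rejection reproduces the prior distribution (KS)", {
  spec <- toy_spec_m1(100, 2000)
  tab <- simulate_batch(spec, 800, 8, seed = 15)
  obs <- as.numeric(tab[1, grep("^xi_", names(tab))])
  summ <- build_summary(obs, tab)
  rej <- abc_reject(summ, nrow(tab))
  set.seed(16)
  prior_draws <- runif(800, 100, 2000)
  ks <- suppressWarnings(ks.test(rej$params$N, prior_draws))
  expect_gt(ks$p.value, 0.01)
})

test_that("duplicated tables accept the same multiset at doubled n_accept", {
  # continuous summaries: distances are a.s. distinct, so the accepted
  # multiset is well defined and invariant under table duplication
  set.seed(21)
  tab <- data.frame(model = "M1", N = runif(200, 100, 2000),
                    xi_1 = rnorm(200), xi_2 = rnorm(200), xi_3 = rnorm(200))
  obs <- c(0.5, 0.5, 0.5)
  s1 <- build_summary(obs, tab)
  r1 <- abc_reject(s1, 50, seed = 2)
  dup <- rbind(tab, tab)
  s2 <- build_summary(obs, dup)
  r2 <- abc_reject(s2, 100, seed = 2)
  expect_equal(sort(r2$params$N), sort(rep(r1$params$N, 2)),
               tolerance = 1e-12)
  expect_equal(r1$tol, r2$tol, tolerance = 1e-12)
})

test_that("logistic and rejection posteriors agree on symmetric problems", {
  # two identically specified models differing only in label
  spec_a <- toy_spec_m1()
  tab_a <- simulate_batch(spec_a, 400, 8, seed = 31)
  tab_b <- simulate_batch(spec_a, 400, 8, seed = 32)
  tab_b$model <- "M1b"
  comb <- bind_ref_tables(list(tab_a, tab_b))
  set.seed(33)
  diffs <- replicate(30, {
    pod <- simulate_batch(spec_a, 1, 8,
                          seed = sample.int(.Machine$integer.max, 1))
    obs <- as.numeric(pod[1, grep("^xi_", names(pod))])
    if (all(obs == 0)) return(NA_real_)
    summ <- build_summary(obs, comb)
    pl <- suppressWarnings(model_choice_logistic(summ, n_keep = 200))
    pr <- model_posterior_rejection(abc_reject(summ, 200))
    pl["M1"] - pr["M1"]
  })
  # both methods hover near 0.5 for exchangeable models
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.1)
})

test_that("model choice probabilities are a proper distribution", {
  tabs <- make_toy_tables()
  comb <- bind_ref_tables(tabs)
  pod <- simulate_batch(toy_spec_m4(), 1, 8, seed = 41)
  obs <- as.numeric(pod[1, grep("^xi_", names(pod))])
  summ <- build_summary(obs, comb)
  p <- suppressWarnings(model_choice_logistic(summ, n_keep = 150, seed = 1))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_named(p, c("M1", "M4"))
})

test_that("logtan maps the support to the line and round-trips to 1e-9", {
  pr <- uniform_prior(20, 20000)
  expect_equal(logtan((20 + 20000) / 2, pr), 0, tolerance = 1e-12)
  set.seed(51)
  x <- runif(1000, 20 + 1e-6, 20000 - 1e-6)
  expect_equal(logtan_inverse(logtan(x, pr), pr), x, tolerance = 1e-9)
  # monotone increasing, diverging at the bounds
  xs <- seq(21, 19999, length.out = 50)
  expect_true(all(diff(logtan(xs, pr)) > 0))
  expect_lt(logtan(20.0000001, pr), -10)
  expect_warning(logtan(20, pr), "clamped")
})

test_that("regression adjustment recovers a noiseless linear map with R2 near 1", {
  # parameter x in (0, 1); summary = logtan(x) exactly
  set.seed(61)
  pr <- uniform_prior(0, 1)
  x <- runif(500, 0.05, 0.95)
  y <- logtan(x, pr) + 10   # offset keeps the observed category positive
  tab <- data.frame(model = "M1", N = x, xi_1 = y, xi_2 = rnorm(500))
  truth <- 0.42
  obs_summary <- c(logtan(truth, pr) + 10, 1)
  summ <- build_summary(obs_summary, tab)
  rej <- abc_reject(summ, 200, seed = 3)
  post <- local_linear_adjust(rej, summ, list(N = pr))
  est <- post$parameters$N
  expect_gt(est$r2, 0.95)
  expect_equal(est$median, truth, tolerance = 0.01)
  expect_lt(est$ci[2] - est$ci[1], 0.05)
})

test_that("uninformative summaries leave the rejection posterior unchanged", {
  set.seed(71)
  pr <- uniform_prior(10, 50)
  x <- runif(400, 10.1, 49.9)
  tab <- data.frame(model = "M1", N = x,
                    xi_1 = rnorm(400), xi_2 = rnorm(400))
  summ <- build_summary(c(0.5, 0.5), tab)
  rej <- abc_reject(summ, 150, seed = 4)
  post <- local_linear_adjust(rej, summ, list(N = pr))
  est <- post$parameters$N
  expect_lt(est$r2, 0.1)
  # adjusted sample stays close to the accepted (prior-like) sample
  expect_equal(median(est$sample), median(rej$params$N), tolerance = 3)
  # support contract: all adjusted values inside the prior
  expect_true(all(est$sample > 10 & est$sample < 50))
})

test_that("adjusted samples always respect the prior support", {
  tabs <- make_toy_tables()
  pod <- simulate_batch(toy_spec_m4(), 1, 8, seed = 81)
  obs <- as.numeric(pod[1, grep("^xi_", names(pod))])
  summ <- build_summary(obs, tabs$M4)
  rej <- abc_reject(summ, 100, seed = 5)
  post <- local_linear_adjust(rej, summ, toy_spec_m4()$priors)
  for (p in names(toy_spec_m4()$priors)) {
    pr <- toy_spec_m4()$priors[[p]]
    expect_true(all(post$parameters[[p]]$sample >= pr$lower))
    expect_true(all(post$parameters[[p]]$sample <= pr$upper))
    ci <- post$parameters[[p]]$ci
    expect_gte(ci[1], pr$lower)
    expect_lte(ci[2], pr$upper)
  }
  # derived T1 recomposed from T2 + LEX
  expect_equal(post$parameters$T1$sample,
               post$parameters$T2$sample + post$parameters$LEX$sample)
})

test_that("time-parameter posteriors stay wide when summaries barely constrain them", {
  spec <- toy_spec_m4()
  tab <- simulate_batch(spec, 600, 8, seed = 91)
  pod <- simulate_batch(spec, 1, 8, seed = 92)
  obs <- as.numeric(pod[1, grep("^xi_", names(pod))])
  summ <- build_summary(obs, tab)
  rej <- abc_reject(summ, 150, seed = 6)
  post <- local_linear_adjust(rej, summ, spec$priors)
  t1 <- post$parameters$T1
  prior_width <- (spec$priors$T2$upper + spec$priors$LEX$upper) -
    (spec$priors$T2$lower + spec$priors$LEX$lower)
  expect_gt((t1$ci[2] - t1$ci[1]) / prior_width, 0.5)
})

test_that("power analysis rows are probability vectors", {
  tabs <- make_toy_tables(400, 8)
  pw <- power_analysis(list(M1 = toy_spec_m1(), M4 = toy_spec_m4()),
                       tabs, n_pods = 15, n = 8, n_keep = 150, seed = 7)
  expect_equal(unname(rowSums(pw$rates)), c(1, 1))
  expect_true(all(pw$rates >= 0 & pw$rates <= 1))
})

test_that("the ABC pipeline is deterministic under a fixed root seed", {
  tabs <- make_toy_tables(300, 8)
  pod <- simulate_batch(toy_spec_m4(), 1, 8, seed = 101)
  obs <- as.numeric(pod[1, grep("^xi_", names(pod))])
  f1 <- abc_fit(obs, tabs, list(M1 = toy_spec_m1(), M4 = toy_spec_m4()),
                n_accept = 100, seed = 17)
  f2 <- abc_fit(obs, tabs, list(M1 = toy_spec_m1(), M4 = toy_spec_m4()),
                n_accept = 100, seed = 17)
  expect_identical(f1$model_posterior_logistic, f2$model_posterior_logistic)
  expect_identical(f1$parameters$parameters$NC$sample,
                   f2$parameters$parameters$NC$sample)
})
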