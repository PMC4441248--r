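# Model specifications, prior sampling and piecewise demographies.

test_that("degenerate and invalid priors are rejected at construction", {
  expect_error(uniform_prior(5, 5), "lower < upper")
  expect_error(uniform_prior(10, 2), "lower < upper")
  expect_error(uniform_prior(-1, 2), "non-negative")
  expect_error(model_spec("M1", priors = list(X = uniform_prior(1, 2))),
               "requires priors exactly")
  expect_error(model_spec("M9"))
  # LGM bound: T2 + LEX may not exceed 20,000 y / generation time
  expect_error(
    model_spec("M2", priors = list(NA_ = uniform_prior(1001, 20000),
                                   NBOT = uniform_prior(20, 1000),
                                   LEX = uniform_prior(5, 1000),
                                   T2 = uniform_prior(0, 30))),
    "LGM")
})

test_that("prior draws respect their supports and T1 is derived", {
  spec1 <- model_spec("M1")
  spec2 <- model_spec("M2")
  for (i in 1:200) {
    p <- sample_prior(spec1, seed = i)
    expect_gte(p$values["N"], 20)
    expect_lte(p$values["N"], 20000)
    expect_gt(p$mu, 0)
    q <- sample_prior(spec2, seed = i)
    expect_gte(q$values["LEX"], 5)
    expect_lte(q$values["LEX"], 634)
    expect_gte(q$values["T2"], 0)
    expect_lte(q$values["T2"], 30)
    expect_equal(q$T1, unname(q$values["T2"] + q$values["LEX"]))
    expect_lte(q$T1, 20000 / 30)
  }
  # mutation-rate prior centred on the study mean
  mus <- vapply(1:500, function(i) sample_prior(spec1, seed = 1000 + i)$mu,
                numeric(1))
  expect_equal(mean(mus), 3.01e-8, tolerance = 0.02)
  expect_equal(sd(mus), 1.25e-9, tolerance = 0.15)
})

test_that("build_demography compiles each model to the right epoch layout", {
  # M1: one constant epoch
  d1 <- build_demography(list(model_id = "M1", values = c(N = 5000)))
  expect_equal(nrow(d1$epochs), 1)
  expect_equal(d1$epochs$mode, "constant")
  expect_equal(demography_size(d1, c(0, 1e6)), c(5000, 5000))

  # M4: constant(recent) / exponential / constant(ancient), with the
  # closed-form log-linear size inside the exponential epoch
  d4 <- build_demography(list(model_id = "M4",
                              values = c(NA_ = 500, NC = 10000,
                                         T2 = 10, LEX = 100)))
  expect_equal(nrow(d4$epochs), 3)
  expect_equal(demography_size(d4, 0), 10000)
  expect_equal(demography_size(d4, 5), 10000)
  expect_equal(demography_size(d4, 60), 10000 * (500 / 10000)^((60 - 10) / 100))
  expect_equal(demography_size(d4, 60), 2236.068, tolerance = 1e-6)
  expect_equal(demography_size(d4, 111), 500)

  # T2 = 0 collapses the recent constant epoch
  d2 <- build_demography(list(model_id = "M2",
                              values = c(NA_ = 10000, NBOT = 100,
                                         T2 = 0, LEX = 50)))
  expect_equal(nrow(d2$epochs), 2)
  expect_equal(d2$epochs$t_recent[1], 0)
  expect_equal(d2$epochs$mode[1], "exponential")

  # M3/M5: two exponential epochs reaching the present
  d3 <- build_demography(list(model_id = "M3",
                              values = c(NA_ = 15000, NER = 50, NC = 8000,
                                         T2 = 20, LEX = 300)))
  expect_equal(nrow(d3$epochs), 3)
  expect_equal(demography_size(d3, 0), 8000)
  expect_equal(demography_size(d3, 20), 50, tolerance = 1e-9)
  expect_equal(demography_size(d3, 320.0001), 15000)

  expect_error(build_demography(list(model_id = "M7", values = c(N = 1))),
               "unknown model_id")
})

test_that("size trajectories are continuous at interior epoch boundaries", {
  vals <- list(
    M2 = c(NA_ = 12000, NBOT = 300, T2 = 15, LEX = 200),
    M3 = c(NA_ = 9000, NER = 120, NC = 14000, T2 = 25, LEX = 400),
    M4 = c(NA_ = 400, NC = 18000, T2 = 8, LEX = 90),
    M5 = c(NA_ = 150, NEE = 16000, NC = 700, T2 = 12, LEX = 500))
  for (m in names(vals)) {
    d <- build_demography(list(model_id = m, values = vals[[m]]))
    ep <- d$epochs
    for (b in ep$t_recent[-1]) {
      eps <- 1e-7 * max(1, b)
      expect_equal(demography_size(d, b - eps), demography_size(d, b + eps),
                   tolerance = 1e-4,
                   label = paste(m, "boundary", b))
    }
  }
})

test_that("piecewise_demography enforces its structural invariants", {
  ep <- function(...) data.frame(...)
  expect_error(piecewise_demography(
    ep(t_recent = 1, t_ancient = Inf, size_recent = 1, size_ancient = 1,
       mode = "constant")), "start at t = 0")
  expect_error(piecewise_demography(
    ep(t_recent = 0, t_ancient = 10, size_recent = 1, size_ancient = 1,
       mode = "constant")), "Inf")
  expect_error(piecewise_demography(
    ep(t_recent = c(0, 20), t_ancient = c(10, Inf),
       size_recent = c(1, 1), size_ancient = c(1, 1),
       mode = c("constant", "constant"))), "contiguous")
  expect_error(piecewise_demography(
    ep(t_recent = 0, t_ancient = Inf, size_recent = 0, size_ancient = 0,
       mode = "constant")), "positive")
})
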