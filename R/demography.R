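# Demographic model specifications and piecewise size trajectories.
#
# Five single-population histories for a non-recombining haploid locus are
# supported.  All population sizes are haploid effective sizes (for MSY
# data, the male effective number); times run backwards from the present in
# generations.
#
#   M1: constant size N.
#   M2: recent constant size NBOT, an exponential reduction (forward in
#       time) spanning LEX generations that started T1 = T2 + LEX
#       generations ago, ancient constant size NA_ ( > NBOT ).
#   M3: as M2 but the reduction (NA_ -> NER) is followed by an expansion
#       from NER to the current size NC over the last T2 generations.
#   M4: mirror of M2 -- an expansion from a small ancient size NA_ to a
#       large current size NC.
#   M5: mirror of M3 -- an expansion (NA_ -> NEE) followed by a reduction
#       to a small current size NC.
#
# "NA_" is used for the ancient-size parameter name to avoid R's missing
# value literal.

MODEL_PARAMS <- list(
  M1 = "N",
  M2 = c("NA_", "NBOT", "LEX", "T2"),
  M3 = c("NA_", "NER", "NC", "LEX", "T2"),
  M4 = c("NA_", "NC", "LEX", "T2"),
  M5 = c("NA_", "NEE", "NC", "LEX", "T2")
)

#' Uniform prior on a scalar parameter
#'
#' @param lower,upper Bounds; `lower < upper` and `lower >= 0` (time
#'   parameters may start at zero).
#' @return An object of class `uniform_prior`.
#' @export
uniform_prior <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1,
            length(upper) == 1, is.finite(lower), is.finite(upper))
  if (!(lower < upper)) {
    stop("uniform prior requires lower < upper (got [", lower, ", ", upper,
         "])")
  }
  if (lower < 0) stop("prior bounds must be non-negative")
  structure(list(lower = lower, upper = upper), class = "uniform_prior")
}

#' @export
print.uniform_prior <- function(x, ...) {
  cat(sprintf("Uniform(%g, %g)\n", x$lower, x$upper))
  invisible(x)
}

default_priors <- function(model_id) {
  u <- uniform_prior
  switch(model_id,
    M1 = list(N = u(20, 20000)),
    M2 = list(NA_ = u(1001, 20000), NBOT = u(20, 1000),
              LEX = u(5, 634), T2 = u(0, 30)),
    M3 = list(NA_ = u(1001, 20000), NER = u(20, 1000), NC = u(1001, 20000),
              LEX = u(5, 634), T2 = u(0, 30)),
    M4 = list(NA_ = u(20, 1000), NC = u(1001, 20000),
              LEX = u(5, 634), T2 = u(0, 30)),
    M5 = list(NA_ = u(20, 1000), NEE = u(1001, 20000), NC = u(20, 1000),
              LEX = u(5, 634), T2 = u(0, 30)),
    stop("unknown model_id: ", model_id)
  )
}

#' Demographic model specification
#'
#' Bundles a model identifier (M1--M5), the uniform priors on its
#' parameters, the generation time, the locus length and the Normal prior
#' on the per-site per-generation mutation rate.  Defaults are the study
#' conditions for European MSY resequencing data: a 3,724,156 bp locus, a
#' 30-year generation time, and a mutation-rate prior with mean
#' 3.01e-8 and sd 1.25e-9 per site per generation (the sd recovers the
#' stated 95% CI 2.77--3.26e-8 as mean +/- 1.96 sd).
#'
#' The Last Glacial Maximum (about 20,000 years ago) bounds the oldest
#' demographic change: `max(T2) + max(LEX)` may not exceed
#' 20,000 / generation_time generations.
#'
#' @param model_id One of `"M1"`..`"M5"`.
#' @param priors Named list of [uniform_prior()] objects; defaults to the
#'   study priors for the model.
#' @param generation_time_years Generation time in years (default 30).
#' @param locus_length_bp Locus length in bp (default 3,724,156).
#' @param mu_prior List with `mean` and `sd` of the Normal mutation-rate
#'   prior (per site per generation), truncated at zero when sampled.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' spec <- model_spec("M1")
#' spec$priors$N
model_spec <- function(model_id,
                       priors = NULL,
                       generation_time_years = 30,
                       locus_length_bp = 3724156L,
                       mu_prior = list(mean = 3.01e-8, sd = 1.25e-9)) {
  model_id <- match.arg(model_id, names(MODEL_PARAMS))
  if (is.null(priors)) priors <- default_priors(model_id)
  wanted <- MODEL_PARAMS[[model_id]]
  if (!setequal(names(priors), wanted)) {
    stop("model ", model_id, " requires priors exactly for {",
         paste(wanted, collapse = ", "), "}")
  }
  ok <- vapply(priors, inherits, logical(1), what = "uniform_prior")
  if (!all(ok)) stop("all priors must be uniform_prior objects")
  stopifnot(generation_time_years > 0, locus_length_bp >= 1,
            mu_prior$mean > 0, mu_prior$sd > 0)
  if (all(c("T2", "LEX") %in% names(priors))) {
    t1_max <- priors$T2$upper + priors$LEX$upper
    lgm_gen <- 20000 / generation_time_years
    if (t1_max > lgm_gen) {
      stop(sprintf(
        "max(T2) + max(LEX) = %.1f generations exceeds the LGM bound of %.2f",
        t1_max, lgm_gen))
    }
  }
  structure(
    list(model_id = model_id,
         priors = priors[wanted],
         generation_time_years = generation_time_years,
         locus_length_bp = as.integer(locus_length_bp),
         mu_prior = mu_prior),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Demographic model", x$model_id, "\n")
  for (p in names(x$priors)) {
    cat(sprintf("  %-5s ~ Uniform(%g, %g)\n", p,
                x$priors[[p]]$lower, x$priors[[p]]$upper))
  }
  cat(sprintf("  mu    ~ Normal(%.3g, %.3g), truncated at 0\n",
              x$mu_prior$mean, x$mu_prior$sd))
  cat(sprintf("  locus %s bp, generation time %g y\n",
              format(x$locus_length_bp, big.mark = ","),
              x$generation_time_years))
  invisible(x)
}

#' Default specifications for the five demographic models
#'
#' @inheritParams model_spec
#' @return Named list of [model_spec()] objects, `M1`..`M5`.
#' @export
default_model_specs <- function(generation_time_years = 30,
                                locus_length_bp = 3724156L,
                                mu_prior = list(mean = 3.01e-8, sd = 1.25e-9)) {
  ids <- names(MODEL_PARAMS)
  stats::setNames(lapply(ids, model_spec,
                         generation_time_years = generation_time_years,
                         locus_length_bp = locus_length_bp,
                         mu_prior = mu_prior), ids)
}

#' Draw one parameter set from a model's priors
#'
#' Each demographic parameter is drawn independently from its uniform
#' prior; the mutation rate is drawn from the Normal prior truncated to
#' (0, Inf).  For models with time parameters, the onset of the oldest
#' change is derived as `T1 = T2 + LEX` (never sampled independently).
#'
#' @param spec A [model_spec()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A list of class `demography_params` with elements `model_id`,
#'   `values` (named numeric), `T1` (derived, or `NA` for M1) and `mu`.
#' @export
sample_prior <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  maybe_set_seed(seed)
  values <- vapply(spec$priors, function(p) stats::runif(1, p$lower, p$upper),
                   numeric(1))
  mu <- -1
  while (mu <= 0) {
    mu <- stats::rnorm(1, spec$mu_prior$mean, spec$mu_prior$sd)
  }
  t1 <- if (all(c("T2", "LEX") %in% names(values)))
    unname(values["T2"] + values["LEX"]) else NA_real_
  structure(list(model_id = spec$model_id, values = values,
                 T1 = t1, mu = mu),
            class = "demography_params")
}

#' Piecewise population-size trajectory
#'
#' Contiguous epochs in backwards time.  Each epoch is constant or
#' exponential; exponential epochs interpolate log-linearly in size between
#' the epoch endpoint sizes.  The most ancient epoch is constant and
#' extends to infinity.
#'
#' @param epochs data.frame with columns `t_recent`, `t_ancient` (in
#'   generations ago), `size_recent`, `size_ancient` and `mode`
#'   (`"constant"` or `"exponential"`).
#' @return Object of class `piecewise_demography`.
#' @export
piecewise_demography <- function(epochs) {
  stopifnot(is.data.frame(epochs),
            all(c("t_recent", "t_ancient", "size_recent", "size_ancient",
                  "mode") %in% names(epochs)))
  ne <- nrow(epochs)
  stopifnot(ne >= 1)
  if (epochs$t_recent[1] != 0) stop("first epoch must start at t = 0")
  if (is.finite(epochs$t_ancient[ne])) stop("last epoch must extend to +Inf")
  if (epochs$mode[ne] != "constant") stop("the most ancient epoch must be constant")
  if (ne > 1 && any(abs(epochs$t_ancient[-ne] - epochs$t_recent[-1]) > 1e-9)) {
    stop("epochs must be contiguous")
  }
  if (any(epochs$size_recent <= 0) || any(epochs$size_ancient <= 0)) {
    stop("population sizes must be positive")
  }
  cst <- epochs$mode == "constant"
  if (any(epochs$size_recent[cst] != epochs$size_ancient[cst])) {
    stop("constant epochs need size_recent == size_ancient")
  }
  if (!all(epochs$mode %in% c("constant", "exponential"))) {
    stop("mode must be 'constant' or 'exponential'")
  }
  structure(list(epochs = epochs), class = "piecewise_demography")
}

#' Compile sampled parameters into a piecewise demography
#'
#' @param params A `demography_params` object from [sample_prior()], or a
#'   list with `model_id` and `values`.
#' @return A [piecewise_demography()].
#' @export
#' @examples
#' p <- list(model_id = "M4",
#'           values = c(NA_ = 500, NC = 10000, T2 = 10, LEX = 100))
#' d <- build_demography(p)
#' demography_size(d, 60)  # about 2236.07
build_demography <- function(params) {
  v <- params$values
  mk <- function(tr, ta, sr, sa, mode) {
    data.frame(t_recent = tr, t_ancient = ta, size_recent = sr,
               size_ancient = sa, mode = mode, stringsAsFactors = FALSE)
  }
  epochs <- switch(params$model_id,
    M1 = mk(0, Inf, v["N"], v["N"], "constant"),
    M2 = ,
    M4 = {
      recent <- if (params$model_id == "M2") v["NBOT"] else v["NC"]
      t2 <- v["T2"]; t1 <- v["T2"] + v["LEX"]
      rows <- list()
      if (t2 > 0) rows <- c(rows, list(mk(0, t2, recent, recent, "constant")))
      rows <- c(rows,
                list(mk(t2, t1, recent, v["NA_"], "exponential")),
                list(mk(t1, Inf, v["NA_"], v["NA_"], "constant")))
      do.call(rbind, rows)
    },
    M3 = ,
    M5 = {
      mid <- if (params$model_id == "M3") v["NER"] else v["NEE"]
      t2 <- v["T2"]; t1 <- v["T2"] + v["LEX"]
      rows <- list()
      if (t2 > 0) rows <- c(rows, list(mk(0, t2, v["NC"], mid, "exponential")))
      rows <- c(rows,
                list(mk(t2, t1, mid, v["NA_"], "exponential")),
                list(mk(t1, Inf, v["NA_"], v["NA_"], "constant")))
      do.call(rbind, rows)
    },
    stop("unknown model_id: ", params$model_id)
  )
  rownames(epochs) <- NULL
  piecewise_demography(epochs)
}

#' Population size at a time in the past
#'
#' @param demo A [piecewise_demography()].
#' @param t Vector of times in generations ago (>= 0).
#' @return Haploid effective size at each time.
#' @export
demography_size <- function(demo, t) {
  stopifnot(inherits(demo, "piecewise_demography"), all(t >= 0))
  ep <- demo$epochs
  vapply(t, function(ti) {
    i <- which(ti >= ep$t_recent & ti < ep$t_ancient)[1]
    if (is.na(i)) i <- nrow(ep)
    if (ep$mode[i] == "constant") return(ep$size_recent[i])
    frac <- (ti - ep$t_recent[i]) / (ep$t_ancient[i] - ep$t_recent[i])
    ep$size_recent[i] * (ep$size_ancient[i] / ep$size_recent[i])^frac
  }, numeric(1))
}

#' @export
print.piecewise_demography <- function(x, ...) {
  cat("Piecewise demography (", nrow(x$epochs), "epochs, generations ago):\n")
  print(x$epochs, row.names = FALSE)
  invisible(x)
}
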