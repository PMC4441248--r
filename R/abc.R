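# Approximate Bayesian computation on derived-SFS summaries: masking and
# scaling, rejection, logistic-regression model choice, logtan-transformed
# local-linear regression adjustment with per-parameter R^2, and power /
# coverage validation on pseudo-observed datasets.

#' Mask and scale summary statistics
#'
#' Retains only SFS categories with at least one observed polymorphic site
#' and scales every retained category by its median absolute deviation
#' across the reference table (categories with zero MAD are scaled by 1).
#' The same mask and scale apply to the observed vector and every
#' simulated row.
#'
#' @param observed_sfs Observed derived SFS ([compute_derived_sfs()] output
#'   or a plain numeric vector `xi_1..xi_{n-1}`).
#' @param table A `ref_table` (possibly combined across models).
#' @return Object of class `abc_summary`: `observed` (scaled), `summaries`
#'   (scaled matrix), `mask`, `scale`, `model` (per row), `params` (per-row
#'   parameter data.frame).
#' @export
build_summary <- function(observed_sfs, table) {
  obs <- as.numeric(observed_sfs)
  if (!length(obs) || all(obs == 0)) stop("observed SFS is empty")
  xi_cols <- grep("^xi_", names(table), value = TRUE)
  if (length(obs) != length(xi_cols)) {
    stop("observed SFS has ", length(obs), " categories but the table has ",
         length(xi_cols))
  }
  mask <- which(obs > 0)
  sims <- as.matrix(table[xi_cols])[, mask, drop = FALSE]
  scale <- apply(sims, 2, stats::mad)
  scale[scale == 0] <- 1
  par_cols <- setdiff(names(table), c("model", xi_cols))
  structure(list(
    observed = obs[mask] / scale,
    summaries = sweep(sims, 2, scale, "/"),
    mask = mask,
    scale = scale,
    model = table$model,
    params = table[par_cols]),
    class = "abc_summary")
}

#' Rejection step
#'
#' Euclidean distance between the scaled observed summary and every
#' reference row; keeps the `n_accept` nearest.  Ties at the acceptance
#' boundary are broken by row order after a seeded shuffle.
#'
#' @param summ An `abc_summary` from [build_summary()].
#' @param n_accept Number of rows to accept (> 0, <= rows).
#' @param seed Optional integer seed for the tie-break shuffle.
#' @return Object of class `abc_rejection`: `index`, `dist` (accepted
#'   distances), `tol` (max accepted distance), `model`, `params`.
#' @export
abc_reject <- function(summ, n_accept, seed = NULL) {
  stopifnot(inherits(summ, "abc_summary"))
  nr <- nrow(summ$summaries)
  if (n_accept <= 0) stop("n_accept must be > 0")
  if (n_accept > nr) stop("n_accept exceeds the table size")
  d <- sqrt(colSums((t(summ$summaries) - summ$observed)^2))
  maybe_set_seed(seed)
  ord <- order(d, sample.int(nr))
  idx <- ord[seq_len(n_accept)]
  structure(list(index = idx, dist = d[idx], tol = max(d[idx]),
                 all_dist = d,
                 model = summ$model[idx],
                 params = summ$params[idx, , drop = FALSE]),
            class = "abc_rejection")
}

#' Model posterior from rejection counts
#'
#' @param rej An `abc_rejection`.
#' @return Named probability vector (class `model_posterior`, method
#'   "rejection").
#' @export
model_posterior_rejection <- function(rej) {
  stopifnot(inherits(rej, "abc_rejection"), length(rej$index) > 0)
  p <- table(rej$model) / length(rej$model)
  structure(as.numeric(p), names = names(p),
            class = "model_posterior", method = "rejection")
}

#' Model choice by multinomial logistic regression
#'
#' Fits a multinomial logistic regression of the model label on the scaled
#' summaries over the `n_keep` rows nearest to the observation and
#' evaluates it at the observed summary.  A small ridge penalty (`decay`)
#' stabilizes the fit under (quasi-)separation.  Models absent from the
#' kept rows get probability 0 with a warning.
#'
#' @param summ An `abc_summary` built from a combined multi-model table.
#' @param n_keep Rows entering the regression (default 1% of the table).
#' @param seed Optional seed (tie-break shuffle in the inner rejection).
#' @param decay Ridge penalty passed to [nnet::multinom()].
#' @return Named probability vector (class `model_posterior`, method
#'   "logistic").
#' @export
model_choice_logistic <- function(summ, n_keep = NULL, seed = NULL,
                                  decay = 1e-4) {
  stopifnot(inherits(summ, "abc_summary"))
  all_models <- sort(unique(summ$model))
  if (length(all_models) < 2) stop("model choice needs >= 2 models")
  n_keep <- n_keep %||% max(2L, ceiling(0.01 * nrow(summ$summaries)))
  rej <- abc_reject(summ, n_keep, seed = seed)
  kept_models <- sort(unique(rej$model))
  if (length(kept_models) < 2) {
    warning("only one model among the kept rows; returning degenerate posterior")
    p <- stats::setNames(as.numeric(all_models == kept_models), all_models)
    return(structure(p, class = "model_posterior", method = "logistic"))
  }
  dat <- as.data.frame(summ$summaries[rej$index, , drop = FALSE])
  names(dat) <- paste0("s", seq_along(dat))
  dat$.model <- factor(rej$model, levels = kept_models)
  fit <- nnet::multinom(.model ~ ., data = dat, trace = FALSE,
                        decay = decay, maxit = 500,
                        MaxNWts = 5000)
  newd <- as.data.frame(t(summ$observed))
  names(newd) <- paste0("s", seq_len(ncol(newd)))
  pr <- stats::predict(fit, newdata = newd, type = "probs")
  if (length(kept_models) == 2) {
    pr <- c(1 - pr, pr)  # multinom returns P(second level) for 2 classes
  }
  p <- stats::setNames(numeric(length(all_models)), all_models)
  p[kept_models] <- as.numeric(pr)
  if (!setequal(kept_models, all_models)) {
    warning("models absent from the kept rows reported with probability 0: ",
            paste(setdiff(all_models, kept_models), collapse = ", "))
  }
  p <- p / sum(p)
  structure(p, class = "model_posterior", method = "logistic")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("Model posterior (", attr(x, "method"), "):\n", sep = "")
  print(round(stats::setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' logtan transform of a bounded parameter
#'
#' Maps `x` in (lower, upper) onto the real line through
#' `y = ln(tan(u * pi/2))` with `u = (x - lower) / (upper - lower)`;
#' monotone increasing, so regression-adjusted values always back-transform
#' into the prior support.  Values at or outside the bounds are clamped
#' just inside with a warning.
#'
#' @param x Numeric vector.
#' @param prior A [uniform_prior()].
#' @return Transformed values.
#' @export
logtan <- function(x, prior) {
  stopifnot(inherits(prior, "uniform_prior"))
  w <- prior$upper - prior$lower
  u <- (x - prior$lower) / w
  eps <- .Machine$double.eps
  if (any(u <= 0 | u >= 1)) {
    warning("values at or outside the prior support clamped inside")
    u <- pmin(pmax(u, eps), 1 - eps)
  }
  log(tan(u * pi / 2))
}

#' @rdname logtan
#' @param y Transformed values.
#' @export
logtan_inverse <- function(y, prior) {
  stopifnot(inherits(prior, "uniform_prior"))
  u <- 2 / pi * atan(exp(y))
  prior$lower + u * (prior$upper - prior$lower)
}

#' Local-linear regression adjustment of accepted parameters
#'
#' The Beaumont regression-ABC step: parameters are logtan-transformed to
#' the real line, weighted by an Epanechnikov kernel of distance over the
#' rejection tolerance, regressed linearly on the scaled summaries
#' (centered at the observation), and adjusted as fitted-at-observed plus
#' residuals.  Back-transformed adjusted samples therefore always respect
#' the prior support.  Derived time parameters (`T1 = T2 + LEX`) are
#' recomposed from their adjusted constituents rather than regressed.
#'
#' @param rej An `abc_rejection` over a single model's rows.
#' @param summ The `abc_summary` the rejection came from.
#' @param priors Named list of [uniform_prior()] for every adjusted
#'   parameter (e.g. `spec$priors`).
#' @return Object of class `param_posterior`: per parameter a list with the
#'   adjusted `sample`, `weights`, `median`, `mode`, `ci` (equal-tailed
#'   95%), `r2`; plus `T1` recomposed when T2 and LEX are present, and
#'   `adjusted` flag (FALSE when the design was singular and the rejection
#'   sample was returned unadjusted).
#' @export
local_linear_adjust <- function(rej, summ, priors) {
  stopifnot(inherits(rej, "abc_rejection"), inherits(summ, "abc_summary"))
  if (length(unique(rej$model)) != 1) {
    stop("parameter adjustment operates on a single model's accepted rows")
  }
  pnames <- intersect(names(priors), names(rej$params))
  if (!length(pnames)) stop("no parameters to adjust")
  x <- summ$summaries[rej$index, , drop = FALSE]
  xc <- sweep(x, 2, summ$observed, "-")
  w <- 1 - (rej$dist / rej$tol)^2           # Epanechnikov
  w[w < 0] <- 0
  if (all(w == 0)) w <- rep(1, length(w))   # all accepted at the tolerance
  design <- cbind(1, xc)
  adjusted <- TRUE
  out <- list()
  for (p in pnames) {
    y <- logtan(rej$params[[p]], priors[[p]])
    fit <- stats::lm.wfit(design, y, w)
    beta <- fit$coefficients
    if (anyNA(beta[-1])) {
      bad <- is.na(beta)
      beta[bad] <- 0
      if (all(beta[-1] == 0) && any(bad[-1])) adjusted <- FALSE
    }
    y_adj <- y - as.numeric(xc %*% beta[-1])
    sample_p <- logtan_inverse(y_adj, priors[[p]])
    wm <- w / sum(w)
    ybar <- sum(wm * y)
    ss_tot <- sum(w * (y - ybar)^2)
    ss_res <- sum(w * (y - design %*% beta)^2)
    r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 0
    dens <- suppressWarnings(stats::density(sample_p, weights = wm))
    out[[p]] <- list(
      sample = sample_p, weights = wm,
      median = weighted_quantile(sample_p, wm, 0.5),
      mode = dens$x[which.max(dens$y)],
      ci = weighted_quantile(sample_p, wm, c(0.025, 0.975)),
      r2 = r2)
  }
  if (all(c("T2", "LEX") %in% pnames)) {
    s <- out$T2$sample + out$LEX$sample
    wm <- out$T2$weights
    dens <- suppressWarnings(stats::density(s, weights = wm))
    out$T1 <- list(sample = s, weights = wm,
                   median = weighted_quantile(s, wm, 0.5),
                   mode = dens$x[which.max(dens$y)],
                   ci = weighted_quantile(s, wm, c(0.025, 0.975)),
                   r2 = NA_real_)
  }
  structure(list(parameters = out, adjusted = adjusted,
                 model = rej$model[1], n_accept = length(rej$index)),
            class = "param_posterior")
}

#' @export
print.param_posterior <- function(x, ...) {
  cat(sprintf("Adjusted posterior, model %s (%d accepted%s):\n", x$model,
              x$n_accept, if (x$adjusted) "" else ", unadjusted fallback"))
  for (p in names(x$parameters)) {
    e <- x$parameters[[p]]
    cat(sprintf("  %-5s median %.4g  mode %.4g  95%% CI [%.4g, %.4g]  R2 %.3f\n",
                p, e$median, e$mode, e$ci[1], e$ci[2], e$r2))
  }
  invisible(x)
}

#' Fit models and parameters to an observed SFS
#'
#' Convenience wrapper: logistic (and rejection) model choice over the
#' combined table, then regression-adjusted parameter estimation under the
#' best model (or a requested model).
#'
#' @param observed_sfs Observed derived SFS.
#' @param tables Named list of per-model `ref_table`s.
#' @param specs Named list of [model_spec()]s supplying the priors.
#' @param n_accept Rows accepted for parameter estimation.
#' @param n_keep Rows entering the model-choice regression (default 1% of
#'   the combined table).
#' @param seed Integer seed.
#' @param estimate_model Model to estimate parameters under (default: the
#'   logistic winner).
#' @return List: `model_posterior_logistic`, `model_posterior_rejection`,
#'   `best_model`, `parameters` (a `param_posterior`).
#' @export
abc_fit <- function(observed_sfs, tables, specs, n_accept = 1000,
                    n_keep = NULL, seed = 1, estimate_model = NULL) {
  combined <- bind_ref_tables(tables)
  summ <- build_summary(observed_sfs, combined)
  seeds <- derive_seeds(seed, 3)
  post_log <- model_choice_logistic(summ, n_keep = n_keep, seed = seeds[1])
  rej_all <- abc_reject(summ, n_keep %||%
                          max(2L, ceiling(0.01 * nrow(combined))),
                        seed = seeds[2])
  post_rej <- model_posterior_rejection(rej_all)
  best <- estimate_model %||% names(post_log)[which.max(post_log)]
  tab_best <- tables[[best]]
  summ_best <- build_summary(observed_sfs, tab_best)
  rej_best <- abc_reject(summ_best, min(n_accept, nrow(tab_best)),
                         seed = seeds[3])
  params <- local_linear_adjust(rej_best, summ_best, specs[[best]]$priors)
  list(model_posterior_logistic = post_log,
       model_posterior_rejection = post_rej,
       best_model = best,
       parameters = params)
}

#' Power analysis of ABC model choice
#'
#' Generates pseudo-observed datasets (pods) under each model's prior,
#' runs model choice against the reference tables, and tabulates how often
#' each model is selected: the diagonal gives true-positive rates, the
#' off-diagonal false-positive rates.
#'
#' @param specs Named list of [model_spec()]s.
#' @param tables Named list of per-model `ref_table`s (same names).
#' @param n_pods Pods per model.
#' @param n Sample size of each pod.
#' @param n_keep Rows entering each model-choice regression.
#' @param seed Integer seed.
#' @param method `"logistic"` or `"rejection"`.
#' @return Object of class `power_report`: `rates` (generating model x
#'   selected model matrix, rows summing to 1), `n_pods`.
#' @export
power_analysis <- function(specs, tables, n_pods, n, n_keep = NULL,
                           seed = 1, method = c("logistic", "rejection")) {
  method <- match.arg(method)
  stopifnot(n_pods >= 1, setequal(names(specs), names(tables)))
  ids <- names(specs)
  combined <- bind_ref_tables(tables)
  rates <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  seeds <- derive_seeds(seed, length(ids) * n_pods)
  k <- 0
  for (m in ids) {
    for (r in seq_len(n_pods)) {
      k <- k + 1
      set.seed(seeds[k])
      pod <- simulate_batch(specs[[m]], 1, n,
                            seed = sample.int(.Machine$integer.max, 1))
      obs <- as.numeric(pod[1, grep("^xi_", names(pod))])
      if (all(obs == 0)) next   # uninformative pod: no polymorphic site
      summ <- build_summary(obs, combined)
      post <- if (method == "logistic") {
        suppressWarnings(model_choice_logistic(summ, n_keep = n_keep))
      } else {
        model_posterior_rejection(
          abc_reject(summ, n_keep %||%
                       max(2L, ceiling(0.01 * nrow(combined)))))
      }
      winner <- names(post)[which.max(post)]
      rates[m, winner] <- rates[m, winner] + 1
    }
  }
  rates <- rates / pmax(rowSums(rates), 1)
  structure(list(rates = rates, n_pods = n_pods, method = method),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("ABC model-choice power (%s, %d pods/model):\n", x$method,
              x$n_pods))
  cat("rows: generating model, columns: selected model\n")
  print(round(x$rates, 3))
  invisible(x)
}

#' Credible-interval coverage of the ABC parameter estimates
#'
#' Draws pods with known generating parameters, runs rejection plus
#' regression adjustment, and reports the fraction of pods whose 95%
#' credible interval covers the truth, per parameter.
#'
#' @param spec The generating [model_spec()].
#' @param table Reference table simulated under `spec` (the pods are drawn
#'   afresh, so the table never contains them).
#' @param n_pods Number of pods.
#' @param n Sample size per pod.
#' @param n_accept Accepted rows per pod.
#' @param seed Integer seed.
#' @return Object of class `coverage_report`: per-parameter coverage,
#'   `n_pods` (pods with at least one polymorphic site).
#' @export
parameter_recovery_suite <- function(spec, table, n_pods, n, n_accept,
                                     seed = 1) {
  stopifnot(n_pods >= 1)
  pnames <- names(spec$priors)
  covered <- stats::setNames(numeric(length(pnames)), pnames)
  used <- 0
  seeds <- derive_seeds(seed, n_pods)
  for (r in seq_len(n_pods)) {
    set.seed(seeds[r])
    truth <- sample_prior(spec)
    demo <- build_demography(truth)
    g <- coalescent_sim(demo, n)
    sites <- drop_mutations(g, truth$mu, spec$locus_length_bp)
    obs <- as.numeric(compute_derived_sfs(sites))
    if (all(obs == 0)) next
    summ <- build_summary(obs, table)
    rej <- abc_reject(summ, min(n_accept, nrow(table)))
    post <- local_linear_adjust(rej, summ, spec$priors)
    used <- used + 1
    for (p in pnames) {
      ci <- post$parameters[[p]]$ci
      if (truth$values[p] >= ci[1] && truth$values[p] <= ci[2]) {
        covered[p] <- covered[p] + 1
      }
    }
  }
  structure(list(coverage = covered / max(used, 1), n_pods = used),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("95%% credible-interval coverage over %d pods:\n", x$n_pods))
  print(round(x$coverage, 3))
  invisible(x)
}
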