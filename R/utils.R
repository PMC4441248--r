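# Internal numerical helpers shared across modules.

#' Harmonic-type sums used by theta estimators
#'
#' `a1 = sum(1/i)` and `a2 = sum(1/i^2)` for `i = 1..n`.
#' @noRd
harmonic_sum <- function(n, power = 1) {
  if (n < 1) return(0)
  sum(1 / seq_len(n)^power)
}

#' Log-sum-exp, guarding against -Inf-only input
#' @noRd
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Weighted quantiles of a sample (type-4 style interpolation on the
#' weighted empirical CDF).
#' @noRd
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0))
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1]
    if (is.na(i)) x[length(x)] else x[i]
  }, numeric(1))
}

#' Per-replicate seeds derived from one root seed
#'
#' A single root seed is split into independent child seeds, one per
#' replicate, so batch runs are reproducible and individually replayable.
#' Child seeds stay below 2^31 (R integers are 32-bit).
#' @noRd
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

#' Set the RNG only when a seed is supplied
#' @noRd
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
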