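# Single-population coalescent simulation under a piecewise demography.
#
# With k active lineages at time t (generations ago) the pair-coalescence
# intensity is k(k-1)/2 * 1/N(t).  Waiting times are drawn by time
# rescaling: a unit-rate exponential deviate is inverted through the
# cumulative hazard, which has a closed form inside constant and
# (log-linear) exponential epochs; unconsumed hazard is carried across
# epoch boundaries.

#' Advance to the next coalescence time
#'
#' Inverts the cumulative coalescent hazard for `k` lineages starting from
#' time `t0`, consuming the exponential deviate `e` epoch by epoch.
#' @noRd
next_coalescent_time <- function(demo, k, t0, e) {
  cc <- k * (k - 1) / 2
  ep <- demo$epochs
  for (i in seq_len(nrow(ep))) {
    if (ep$t_ancient[i] <= t0) next
    s <- max(t0, ep$t_recent[i])
    if (ep$mode[i] == "constant") {
      n_sz <- ep$size_recent[i]
      h_full <- if (is.finite(ep$t_ancient[i]))
        cc * (ep$t_ancient[i] - s) / n_sz else Inf
      if (e <= h_full) return(s + e * n_sz / cc)
      e <- e - h_full
    } else {
      nr <- ep$size_recent[i]
      g <- log(ep$size_ancient[i] / nr) / (ep$t_ancient[i] - ep$t_recent[i])
      if (abs(g) < 1e-12) {  # numerically flat epoch
        h_full <- cc * (ep$t_ancient[i] - s) / nr
        if (e <= h_full) return(s + e * nr / cc)
        e <- e - h_full
        next
      }
      a <- exp(-g * (s - ep$t_recent[i]))
      b <- a - e * nr * g / cc
      t_ev <- if (b > 0) ep$t_recent[i] - log(b) / g else Inf
      if (b > 0 && t_ev <= ep$t_ancient[i]) return(t_ev)
      h_epoch <- cc / (nr * g) *
        (a - exp(-g * (ep$t_ancient[i] - ep$t_recent[i])))
      e <- e - h_epoch
    }
  }
  stop("ran out of epochs: demography must end in an infinite constant epoch")
}

#' Simulate a coalescent genealogy
#'
#' Generates an ultrametric genealogy of `n` haploid samples under a
#' piecewise demography.  Tips are nodes `1..n` at time 0; internal nodes
#' `n+1 .. 2n-1` are created in coalescence order, the last being the root.
#'
#' @param demo A [piecewise_demography()].
#' @param n Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @return Object of class `genealogy`: `n_tips`, `parent` (0 for the
#'   root), `time` (generations ago) and `tip_labels`.
#' @export
#' @examples
#' d <- build_demography(list(model_id = "M1", values = c(N = 1000)))
#' g <- coalescent_sim(d, 10, seed = 1)
#' genealogy_tmrca(g)
coalescent_sim <- function(demo, n, seed = NULL) {
  stopifnot(inherits(demo, "piecewise_demography"))
  if (!is.numeric(n) || n < 2) stop("need at least n = 2 tips")
  n <- as.integer(n)
  maybe_set_seed(seed)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)
  t_cur <- 0
  nxt <- n + 1L
  for (k in seq(n, 2L)) {
    t_cur <- next_coalescent_time(demo, k, t_cur, stats::rexp(1))
    pick <- sample.int(length(active), 2L)
    parent[active[pick]] <- nxt
    node_time[nxt] <- t_cur
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  structure(list(n_tips = n, parent = parent, time = node_time,
                 tip_labels = paste0("t", seq_len(n))),
            class = "genealogy")
}

#' Branch table of a genealogy
#'
#' One row per non-root node: the branch from the node up to its parent.
#' @param g A `genealogy`.
#' @return data.frame with `node`, `parent`, `length` (generations).
#' @export
genealogy_branches <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  node <- which(g$parent > 0L)
  data.frame(node = node, parent = g$parent[node],
             length = g$time[g$parent[node]] - g$time[node])
}

#' Tips descending from each node
#'
#' @param g A `genealogy`.
#' @return List over nodes `1..2n-1`; element i holds the tip ids below
#'   node i (a tip is below itself).
#' @export
genealogy_tips_below <- function(g) {
  n <- g$n_tips
  out <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) out[[i]] <- i
  kids <- split(seq_along(g$parent), g$parent)
  for (m in seq(n + 1L, 2L * n - 1L)) {
    out[[m]] <- unlist(out[kids[[as.character(m)]]], use.names = FALSE)
  }
  out
}

#' Total branch length in generations
#' @param g A `genealogy`.
#' @export
genealogy_total_length <- function(g) {
  sum(genealogy_branches(g)$length)
}

#' Time to the most recent common ancestor (root height)
#' @param g A `genealogy`.
#' @export
genealogy_tmrca <- function(g) {
  g$time[2L * g$n_tips - 1L]
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("Coalescent genealogy: %d tips, TMRCA %.1f generations\n",
              x$n_tips, genealogy_tmrca(x)))
  invisible(x)
}
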