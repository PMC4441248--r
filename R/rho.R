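# Rho-statistic TMRCA dating on mutation-count trees.
#
# rho is the mean number of mutations from a clade's root node to its
# tips; multiplied by a scaled rate in years per mutation it dates the
# clade.  Reported ages are rounded half-up at the tens digit.  The standard deviation follows the branch-weight estimator of
# Saillard et al. (2000): sd^2 = sum over branches of (n_b / n)^2 * l_b,
# with n_b the tips below a branch and l_b its mutation count.

#' Parse a Newick tree whose branch lengths are mutation counts
#'
#' @param newick A Newick string, or a file path when `file = TRUE`.
#' @param file Read from a file instead of text.
#' @return Object of class `mutation_tree` wrapping an [ape::read.tree()]
#'   phylo with validated branch counts.
#' @export
parse_mutation_tree <- function(newick, file = FALSE) {
  tr <- if (file) ape::read.tree(file = newick)
        else ape::read.tree(text = newick)
  if (is.null(tr)) stop("malformed Newick input")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length) ||
      any(!is.finite(tr$edge.length))) {
    stop("every branch must carry a mutation count (missing branch length)")
  }
  if (any(tr$edge.length < 0)) stop("negative mutation counts")
  if (any(tr$edge.length %% 1 != 0)) {
    warning("non-integer branch mutation counts (consensus tree averages?)")
  }
  structure(list(phylo = tr), class = "mutation_tree")
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat(sprintf("Mutation-count tree: %d tips, %d total mutations\n",
              length(x$phylo$tip.label), sum(x$phylo$edge.length)))
  invisible(x)
}

#' Resolve a clade to its MRCA node
#'
#' @param tree A `mutation_tree`.
#' @param clade `NULL` (whole tree), an internal-node label, or a character
#'   vector of tip labels whose MRCA defines the clade.
#' @return Internal node number in ape convention.
#' @export
resolve_clade <- function(tree, clade = NULL) {
  tr <- tree$phylo
  ntip <- length(tr$tip.label)
  if (is.null(clade)) return(ntip + 1L)  # root
  if (length(clade) == 1L && !clade %in% tr$tip.label) {
    if (is.null(tr$node.label) || !clade %in% tr$node.label) {
      stop("clade label not found: ", clade)
    }
    return(ntip + which(tr$node.label == clade)[1])
  }
  miss <- setdiff(clade, tr$tip.label)
  if (length(miss)) stop("tips not in tree: ", paste(miss, collapse = ", "))
  if (length(clade) == 1L) return(which(tr$tip.label == clade))
  ape::getMRCA(tr, clade)
}

#' Rho statistic and its standard deviation for a clade
#'
#' @param tree A `mutation_tree`.
#' @param clade See [resolve_clade()].
#' @return List: `rho`, `sd_rho`, `n_tips`.
#' @export
#' @examples
#' tr <- parse_mutation_tree("((a:1,b:1):2,c:4);")
#' rho_statistic(tr)$rho  # 10/3
rho_statistic <- function(tree, clade = NULL) {
  stopifnot(inherits(tree, "mutation_tree"))
  tr <- tree$phylo
  node <- resolve_clade(tree, clade)
  ntip <- length(tr$tip.label)
  if (node <= ntip) {                      # single-tip clade
    return(list(rho = 0, sd_rho = 0, n_tips = 1L))
  }
  # depth of every node below `node`, walking edges in preorder
  depth <- rep(NA_real_, ntip + tr$Nnode)
  depth[node] <- 0
  ord <- ape::reorder.phylo(tr, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; chd <- ord$edge[e, 2]
    if (!is.na(depth[par])) depth[chd] <- depth[par] + ord$edge.length[e]
  }
  in_clade_tip <- which(!is.na(depth[seq_len(ntip)]))
  n <- length(in_clade_tip)
  rho <- mean(depth[in_clade_tip])
  # Saillard variance over branches inside the clade
  tips_below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- i
  post <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chd <- post$edge[e, 2]
    tips_below[[par]] <- c(tips_below[[par]], tips_below[[chd]])
  }
  var_rho <- 0
  for (e in seq_len(nrow(tr$edge))) {
    chd <- tr$edge[e, 2]
    if (is.na(depth[chd]) || chd == node) next
    nb <- length(tips_below[[chd]])
    var_rho <- var_rho + (nb / n)^2 * tr$edge.length[e]
  }
  list(rho = rho, sd_rho = sqrt(var_rho), n_tips = n)
}

#' Scaled rate in years per mutation
#'
#' `years_per_mutation = 1 / (mu * L)` for a per-site per-year rate `mu`
#' and locus length `L`, reported to 0.1 years.  An optional rate CI maps
#' to a (low, high) range of years per mutation (the upper rate bound gives
#' the low year bound).
#'
#' @param mu_per_site_per_year Point mutation rate (> 0).
#' @param L Locus length in bp (>= 1).
#' @param mu_ci Optional length-2 rate CI `(low, high)`.
#' @return Object of class `scaled_rate`: `years_per_mutation` (rounded to
#'   0.1), `range` (rounded), and the unrounded `raw` values.
#' @export
#' @examples
#' scaled_rate(1.0e-9, 3724156, mu_ci = c(0.92e-9, 1.09e-9))
scaled_rate <- function(mu_per_site_per_year, L, mu_ci = NULL) {
  stopifnot(mu_per_site_per_year > 0, L >= 1)
  raw <- 1 / (mu_per_site_per_year * L)
  range_raw <- NULL
  if (!is.null(mu_ci)) {
    stopifnot(length(mu_ci) == 2, all(mu_ci > 0), mu_ci[1] < mu_ci[2])
    range_raw <- c(1 / (mu_ci[2] * L), 1 / (mu_ci[1] * L))
  }
  structure(list(years_per_mutation = round(raw, 1),
                 range = if (is.null(range_raw)) NULL else round(range_raw, 1),
                 raw = list(years_per_mutation = raw, range = range_raw)),
            class = "scaled_rate")
}

#' @export
print.scaled_rate <- function(x, ...) {
  cat(sprintf("Scaled rate: %.1f years/mutation", x$years_per_mutation))
  if (!is.null(x$range)) cat(sprintf(" (%.1f-%.1f)", x$range[1], x$range[2]))
  cat("\n")
  invisible(x)
}

#' TMRCA in years from a rho estimate
#'
#' `TMRCA = rho * years_per_mutation`; the range comes from the rate CI.
#' Reported values are rounded to the nearest 10 years; unrounded values
#' are retained alongside.
#'
#' @param est List with `rho` and optionally `sd_rho`, `n_tips` (as from
#'   [rho_statistic()]), or a single number.
#' @param rate A [scaled_rate()].
#' @return Object of class `rho_estimate`.
#' @export
#' @examples
#' r <- scaled_rate(1.0e-9, 3724156, mu_ci = c(0.92e-9, 1.09e-9))
#' tmrca_from_rho(65, r)$tmrca_years  # 17450
tmrca_from_rho <- function(est, rate) {
  stopifnot(inherits(rate, "scaled_rate"))
  if (is.numeric(est)) est <- list(rho = est)
  stopifnot(est$rho >= 0)
  raw <- est$rho * rate$years_per_mutation
  rng_raw <- if (!is.null(rate$range)) est$rho * rate$range else NULL
  round10 <- function(x) floor(x / 10 + 0.5) * 10  # half-up at the tens digit
  structure(list(rho = est$rho,
                 sd_rho = est$sd_rho %||% NA_real_,
                 n_tips = est$n_tips %||% NA_integer_,
                 tmrca_years = round10(raw),
                 tmrca_years_raw = raw,
                 range_years = if (is.null(rng_raw)) NULL else round10(rng_raw),
                 range_years_raw = rng_raw),
            class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("rho = %.3g (sd %.3g), TMRCA %s years", x$rho, x$sd_rho,
              format(x$tmrca_years, big.mark = ",")))
  if (!is.null(x$range_years)) {
    cat(sprintf(" (%s-%s)", format(x$range_years[1], big.mark = ","),
                format(x$range_years[2], big.mark = ",")))
  }
  cat("\n")
  invisible(x)
}

#' Haplogroup frequency table
#'
#' @param assignments Character/factor vector of per-sample haplogroup
#'   assignments, or a data.frame with columns `haplogroup` and `count`.
#' @return data.frame: `haplogroup`, `count`, `percent` (to 0.1).
#' @export
#' @examples
#' haplogroup_frequencies(data.frame(haplogroup = c("R1b-M269", "other"),
#'                                   count = c(144, 190)))
haplogroup_frequencies <- function(assignments) {
  if (is.data.frame(assignments)) {
    stopifnot(all(c("haplogroup", "count") %in% names(assignments)))
    tab <- assignments
  } else {
    if (!length(assignments)) stop("need at least one assignment")
    t0 <- table(assignments)
    tab <- data.frame(haplogroup = names(t0), count = as.integer(t0))
  }
  stopifnot(all(tab$count >= 0), sum(tab$count) > 0)
  tab$percent <- round(100 * tab$count / sum(tab$count), 1)
  tab[order(-tab$count), , drop = FALSE]
}
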