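# Finite-sites mutation on a genealogy and the derived site frequency
# spectrum.
#
# Mutations are dropped as a Poisson process of rate mu * L over the total
# branch length; each hit lands on a branch with probability proportional
# to branch length, at a position uniform on 1..L, with a 4-state model and
# no transition/transversion bias: the current base is replaced by one of
# the other three with equal probability.  Positions can be hit more than
# once; repeat hits are applied in age order down each lineage, so a site
# may revert in part of the sample or become triallelic.

DNA_BASES <- c("A", "C", "G", "T")

#' Drop finite-sites mutations on a genealogy
#'
#' @param g A `genealogy` from [coalescent_sim()].
#' @param mu Per-site per-generation mutation rate (> 0).
#' @param L Locus length in bp (>= 1).
#' @param seed Optional integer seed.
#' @return Object of class `site_table`: `positions` (1-based, increasing),
#'   `ancestral` (base per site), `alleles` (site x tip character matrix),
#'   `n_mutations` (hits per site), `n_tips`, `L`.
#' @export
drop_mutations <- function(g, mu, L, seed = NULL) {
  stopifnot(inherits(g, "genealogy"))
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0")
  if (L < 1) stop("L must be >= 1")
  L <- as.integer(L)
  maybe_set_seed(seed)
  n <- g$n_tips
  br <- genealogy_branches(g)
  total_len <- sum(br$length)
  m <- stats::rpois(1, mu * L * total_len)
  empty <- function() {
    structure(list(positions = integer(0), ancestral = character(0),
                   alleles = matrix(character(0), 0, n,
                                    dimnames = list(NULL, g$tip_labels)),
                   n_mutations = integer(0), n_tips = n, L = L),
              class = "site_table")
  }
  if (m == 0) return(empty())
  branch <- sample.int(nrow(br), m, replace = TRUE, prob = br$length)
  pos <- sample.int(L, m, replace = TRUE)
  # age of each hit (generations ago), uniform along its branch
  age <- g$time[br$node[branch]] + stats::runif(m) * br$length[branch]
  tips_below <- genealogy_tips_below(g)

  upos <- sort(unique(pos))
  site_of <- match(pos, upos)
  s_all <- length(upos)
  anc <- sample(DNA_BASES, s_all, replace = TRUE)
  hits_per_site <- tabulate(site_of, s_all)
  alleles <- matrix(anc, nrow = s_all, ncol = n)  # recycles anc down columns
  colnames(alleles) <- g$tip_labels

  single <- which(hits_per_site == 1L)
  if (length(single)) {
    mut_idx <- match(single, site_of)
    sub <- tips_below[br$node[branch[mut_idx]]]
    nb <- lengths(sub)
    derived <- vapply(seq_along(single), function(j) {
      sample(setdiff(DNA_BASES, anc[single[j]]), 1)
    }, character(1))
    alleles[cbind(rep(single, nb), unlist(sub, use.names = FALSE))] <-
      rep(derived, nb)
  }
  multi <- which(hits_per_site > 1L)
  for (s in multi) {
    idx <- which(site_of == s)
    idx <- idx[order(age[idx], decreasing = TRUE)]  # oldest first
    for (j in idx) {
      tips <- tips_below[[br$node[branch[j]]]]
      cur <- alleles[s, tips[1]]
      alleles[s, tips] <- sample(setdiff(DNA_BASES, cur), 1)
    }
  }
  seg <- rowSums(alleles != anc) > 0L  # drop fully reverted sites
  structure(list(positions = upos[seg], ancestral = anc[seg],
                 alleles = alleles[seg, , drop = FALSE],
                 n_mutations = hits_per_site[seg], n_tips = n, L = L),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("Site table: %d segregating sites, %d tips, locus %s bp\n",
              length(x$positions), x$n_tips, format(x$L, big.mark = ",")))
  invisible(x)
}

#' Derived site frequency spectrum
#'
#' Counts biallelic polymorphic sites by the number of tips carrying the
#' derived (non-ancestral) allele.  Sites fixed derived (count `n`) carry
#' no within-sample information and are excluded, as are sites with more
#' than one derived allele (triallelic or worse under recurrent mutation).
#'
#' @param sites A `site_table`.
#' @param n Sample size; defaults to the table's tip count.
#' @return Object of class `sfs`: integer vector `xi_1 .. xi_{n-1}`.
#' @export
compute_derived_sfs <- function(sites, n = sites$n_tips) {
  stopifnot(inherits(sites, "site_table"))
  if (n != sites$n_tips) stop("sample size does not match the site table")
  xi <- integer(n - 1L)
  if (length(sites$positions)) {
    dmat <- sites$alleles != sites$ancestral  # anc recycled down columns
    dcount <- rowSums(dmat)
    n_derived_alleles <- Reduce(`+`, lapply(DNA_BASES, function(b) {
      as.integer(rowSums((sites$alleles == b) & dmat) > 0L)
    }))
    keep <- dcount >= 1L & dcount <= n - 1L & n_derived_alleles == 1L
    xi <- tabulate(dcount[keep], nbins = n - 1L)
  }
  structure(as.integer(xi), class = "sfs", n = n,
            names = paste0("xi_", seq_len(n - 1L)))
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("Derived SFS (n = %d, %d sites):\n", attr(x, "n"), sum(x)))
  print(unclass(x))
  invisible(x)
}
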