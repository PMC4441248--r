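# Independent oracles used to cross-check the package implementations.
# Each oracle takes its own route (direct formulas, exact integer
# arithmetic, numerical integration, or ape primitives) and never calls
# the code path it validates.

# Tajima's D recomputed constant-by-constant, written directly from the
# 1989 variance decomposition with explicit loops.
oracle_tajimas_d <- function(S, pi, n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i^2
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

# Direct constant-N coalescent: inter-coalescent waits are plain
# exponentials with rate k(k-1)/(2N); no piecewise machinery involved.
oracle_constant_tmrca <- function(n, N) {
  t <- 0
  for (k in n:2) t <- t + rexp(1, rate = k * (k - 1) / (2 * N))
  t
}

# Generic demography oracle: inverts the cumulative coalescent hazard
# numerically (integrate + uniroot) against a size function supplied as a
# plain R function of time.
oracle_coalescent_tmrca <- function(n, size_fun, t_max = 1e7) {
  t <- 0
  for (k in n:2) {
    e <- rexp(1)
    haz <- function(w) {
      integrate(function(u) (k * (k - 1) / 2) / size_fun(u),
                lower = t, upper = t + w, rel.tol = 1e-9)$value - e
    }
    w_hi <- 1
    while (haz(w_hi) < 0 && w_hi < t_max) w_hi <- w_hi * 2
    t <- t + uniroot(haz, c(1e-12, w_hi), tol = 1e-8)$root
  }
  t
}

# Unsigned Stirling numbers of the first kind by exact expansion of the
# rising factorial x(x+1)...(x+n-1); safe for small n only.
oracle_stirling_row <- function(n) {
  coefs <- c(0, 1)  # polynomial x, coefficients of x^0, x^1
  if (n > 1) {
    for (m in 1:(n - 1)) {
      shifted <- c(0, coefs)                 # * x
      scaled <- c(coefs * m, 0)              # * m
      coefs <- shifted + scaled
    }
  }
  coefs[2:(n + 1)]  # |s(n, k)|, k = 1..n
}

# Chinese-restaurant construction of the Ewens partition: returns the
# number of occupied tables (distinct haplotypes).
oracle_crt_k <- function(n, theta) {
  k <- 1
  counts <- c(1)
  for (i in 2:n) {
    p_new <- theta / (theta + i - 1)
    if (runif(1) < p_new) {
      k <- k + 1
      counts <- c(counts, 1)
    } else {
      j <- sample.int(k, 1, prob = counts)
      counts[j] <- counts[j] + 1
    }
  }
  k
}

# Exhaustive root-to-tip path sums on an ape phylo, via ape's own node
# paths.
oracle_path_sums <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1
  vapply(seq_len(ntip), function(tip) {
    pth <- ape::nodepath(phy, root, tip)
    s <- 0
    for (i in seq_len(length(pth) - 1)) {
      e <- which(phy$edge[, 1] == pth[i] & phy$edge[, 2] == pth[i + 1])
      s <- s + phy$edge.length[e]
    }
    s
  }, numeric(1))
}

# Small toy specifications shared across ABC tests: a narrow constant-size
# model and an old, strong (about 100-fold) expansion, on a 200 kb locus.
toy_spec_m1 <- function(lower = 800, upper = 1200) {
  model_spec("M1", priors = list(N = uniform_prior(lower, upper)),
             locus_length_bp = 2e5)
}
toy_spec_m4 <- function() {
  model_spec("M4",
             priors = list(NA_ = uniform_prior(100, 200),
                           NC = uniform_prior(15000, 20000),
                           LEX = uniform_prior(500, 634),
                           T2 = uniform_prior(20, 30)),
             locus_length_bp = 2e5)
}

constant_demo <- function(N) {
  build_demography(list(model_id = "M1", values = c(N = N)))
}
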