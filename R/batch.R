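# Bulk simulation: prior draw -> demography -> genealogy -> mutations ->
# derived SFS, one row per replicate.  This is the reference-table
# generator feeding the ABC machinery.

#' Simulate a reference table under one demographic model
#'
#' Each replicate draws parameters (including the mutation rate) from the
#' model's priors, simulates a genealogy of `n` tips and finite-sites
#' mutations over the locus, and records the derived SFS.  A single root
#' seed is split into per-replicate seeds, so runs are reproducible and any
#' single row can be replayed.
#'
#' @param spec A [model_spec()].
#' @param n_sims Number of replicates (>= 1).
#' @param n Sample size (tips per replicate).
#' @param seed Root integer seed.
#' @return data.frame of class `ref_table`: `model`, one column per model
#'   parameter, `T1` (derived) where applicable, `mu`, then
#'   `xi_1..xi_{n-1}`.  Attributes: `n`, `seed`, `rep_seeds`.
#' @export
simulate_batch <- function(spec, n_sims, n, seed) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.numeric(n_sims) || n_sims < 1) stop("n_sims must be >= 1")
  n_sims <- as.integer(n_sims)
  n <- as.integer(n)
  rep_seeds <- derive_seeds(seed, n_sims)
  pnames <- names(spec$priors)
  par_mat <- matrix(NA_real_, n_sims, length(pnames),
                    dimnames = list(NULL, pnames))
  t1 <- numeric(n_sims)
  mu <- numeric(n_sims)
  xi <- matrix(0L, n_sims, n - 1L,
               dimnames = list(NULL, paste0("xi_", seq_len(n - 1L))))
  for (i in seq_len(n_sims)) {
    set.seed(rep_seeds[i])
    params <- sample_prior(spec)
    demo <- build_demography(params)
    g <- coalescent_sim(demo, n)
    sites <- drop_mutations(g, params$mu, spec$locus_length_bp)
    xi[i, ] <- compute_derived_sfs(sites)
    par_mat[i, ] <- params$values[pnames]
    t1[i] <- params$T1
    mu[i] <- params$mu
  }
  out <- data.frame(model = spec$model_id, par_mat, T1 = t1, mu = mu,
                    xi, check.names = FALSE)
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  attr(out, "rep_seeds") <- rep_seeds
  class(out) <- c("ref_table", "data.frame")
  out
}

#' Write / read a reference table as tab-separated text
#'
#' Header columns: `model`, the parameter columns, `T1`, `mu`, then
#' `xi_1..xi_{n-1}`.  Gzip is applied when the path ends in `.gz`.
#'
#' @param tab A `ref_table`.
#' @param path Output file.
#' @export
write_ref_table <- function(tab, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ref_table
#' @export
read_ref_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  xi_cols <- grep("^xi_", names(tab))
  if (!length(xi_cols)) stop("no SFS columns (xi_*) in ", path)
  attr(tab, "n") <- length(xi_cols) + 1L
  class(tab) <- c("ref_table", "data.frame")
  tab
}

#' Combine per-model reference tables for model choice
#'
#' Aligns parameter columns (absent parameters become NA) and stacks the
#' tables.
#' @param tables List of `ref_table` objects.
#' @export
bind_ref_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  n <- unique(vapply(tables, function(t) attr(t, "n"), integer(1)))
  if (length(n) != 1) stop("reference tables have differing sample sizes")
  all_cols <- unique(unlist(lapply(tables, names)))
  xi_cols <- grep("^xi_", all_cols, value = TRUE)
  par_cols <- setdiff(all_cols, c("model", xi_cols))
  ordered <- c("model", par_cols, xi_cols)
  filled <- lapply(tables, function(t) {
    missing <- setdiff(ordered, names(t))
    for (m in missing) t[[m]] <- NA_real_
    t[ordered]
  })
  out <- do.call(rbind, filled)
  rownames(out) <- NULL
  attr(out, "n") <- n
  class(out) <- c("ref_table", "data.frame")
  out
}
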