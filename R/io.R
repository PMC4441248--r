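# Cohort I/O: haploid VCF ingest/export, call-set concordance and the
# end-to-end pipeline driver with its run manifest.

#' Read a haploid multi-sample VCF into population samples
#'
#' Genotypes may be haploid ("0", "1") or homozygous diploid ("0/0",
#' "1|1"); homozygous diploid calls collapse to haploid.  Heterozygous
#' calls on a haploid locus are treated as missing with a warning, as is
#' ".".  Samples without a population assignment are dropped with a
#' warning.
#'
#' @param path VCF file (plain or gzipped).
#' @param popmap Two-column data.frame (sample, pop) or path to a
#'   headerless two-column TSV.
#' @return Named list of [population_sample()] objects, one per
#'   population, with a `log` attribute (sites read, heterozygous calls
#'   masked, samples dropped).
#' @export
read_haploid_vcf <- function(path, popmap) {
  if (is.character(popmap)) {
    popmap <- utils::read.table(popmap, header = FALSE, sep = "\t",
                                col.names = c("sample", "pop"),
                                stringsAsFactors = FALSE)
  }
  stopifnot(ncol(popmap) >= 2)
  names(popmap)[1:2] <- c("sample", "pop")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  samples <- colnames(gt)
  absent <- setdiff(popmap$sample, samples)
  if (length(absent)) {
    stop("popmap references samples absent from the VCF: ",
         paste(absent, collapse = ", "))
  }
  unassigned <- setdiff(samples, popmap$sample)
  if (length(unassigned)) {
    warning(length(unassigned), " sample(s) without a population dropped: ",
            paste(unassigned, collapse = ", "))
  }
  ref <- fix[, "REF"]
  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                       fixed = TRUE)
  n_het <- 0L
  base_mat <- matrix(NA_character_, nrow(gt), ncol(gt),
                     dimnames = dimnames(gt))
  first <- sub("[/|].*$", "", gt)
  second <- ifelse(grepl("[/|]", gt), sub("^.*[/|]", "", gt), first)
  het <- !is.na(gt) & first != second
  n_het <- sum(het)
  if (n_het > 0) {
    warning(n_het, " heterozygous call(s) on a haploid locus set to missing")
  }
  idx <- !is.na(gt) & !het & first != "."
  allele_num <- suppressWarnings(as.integer(first))
  for (s in which(rowSums(idx) > 0)) {
    alleles <- c(ref[s], alt_list[[s]])
    cols <- which(idx[s, ])
    base_mat[s, cols] <- alleles[allele_num[(cols - 1L) * nrow(gt) + s] + 1L]
  }
  pos <- as.integer(fix[, "POS"])
  pops <- split(popmap$sample, popmap$pop)
  out <- lapply(names(pops), function(p) {
    population_sample(base_mat[, pops[[p]], drop = FALSE], pop_id = p,
                      positions = pos, individuals = pops[[p]])
  })
  names(out) <- names(pops)
  attr(out, "log") <- list(n_sites = nrow(gt), n_het_masked = n_het,
                           n_samples_dropped = length(unassigned))
  out
}

#' Write population samples to a haploid VCF
#'
#' All populations must share the site set.  The REF allele at each site is
#' the first non-missing call encountered; remaining alleles become ALT.
#' Calls are written as haploid genotype indices, missing as ".".
#'
#' @param samples Named list of [population_sample()] objects.
#' @param path Output path.
#' @param chrom Chromosome name used in the CHROM column.
#' @export
write_haploid_vcf <- function(samples, path, chrom = "Y") {
  stopifnot(length(samples) >= 1)
  alle <- do.call(cbind, lapply(samples, function(s) s$alleles))
  ids <- unlist(lapply(samples, function(s) s$individuals), use.names = FALSE)
  pos <- samples[[1]]$positions
  for (s in samples) stopifnot(identical(s$positions, pos))
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", chrom, ">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i) {
    row <- alle[i, ]
    seen <- unique(row[!is.na(row)])
    if (!length(seen)) stop("site with all calls missing at position ", pos[i])
    ref <- seen[1]
    alt <- setdiff(seen, ref)
    gt <- ifelse(is.na(row), ".", as.character(match(row, seen) - 1L))
    paste(c(chrom, pos[i], ".", ref,
            if (length(alt)) paste(alt, collapse = ",") else ".",
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Haploid call set keyed by site
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param calls Character matrix sites x samples with values `"ref"`,
#'   `"alt"` or `NA`.
#' @param samples Sample ids (defaults to `colnames(calls)`).
#' @return Object of class `call_set`.
#' @export
call_set <- function(sites, calls, samples = colnames(calls)) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(sites) == nrow(calls))
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  if (anyDuplicated(key)) stop("duplicate site keys")
  ok <- calls %in% c("ref", "alt") | is.na(calls)
  if (!all(ok)) stop("calls must be 'ref', 'alt' or NA")
  calls <- matrix(calls, nrow(sites), dimnames = list(key, samples))
  structure(list(sites = sites, key = key, calls = calls,
                 samples = samples), class = "call_set")
}

#' Concordance between two haploid call sets
#'
#' Over the shared samples and site keys, a false positive is a variant
#' (alt) call in `a` where `b` has reference; a false negative is a
#' reference call in `a` where `b` has the variant.  Rates are percentages
#' of the comparable (both non-missing) calls.
#'
#' @param a,b [call_set()] objects; `a` is the set under evaluation, `b`
#'   the control.
#' @return Object of class `concordance_report`: `n_overlap_sites`,
#'   `n_overlap_samples`, `n_comparable`, `false_positive_rate`,
#'   `false_negative_rate` (percent), `discordant` (data.frame).
#' @export
genotype_concordance <- function(a, b) {
  stopifnot(inherits(a, "call_set"), inherits(b, "call_set"))
  sites <- intersect(a$key, b$key)
  samples <- intersect(a$samples, b$samples)
  if (!length(sites) || !length(samples)) {
    stop("call sets share no sites or no samples")
  }
  ca <- a$calls[sites, samples, drop = FALSE]
  cb <- b$calls[sites, samples, drop = FALSE]
  comparable <- !is.na(ca) & !is.na(cb)
  fp <- comparable & ca == "alt" & cb == "ref"
  fn <- comparable & ca == "ref" & cb == "alt"
  disc <- which(fp | fn, arr.ind = TRUE)
  structure(list(
    n_overlap_sites = length(sites),
    n_overlap_samples = length(samples),
    n_comparable = sum(comparable),
    false_positive_rate = 100 * sum(fp) / sum(comparable),
    false_negative_rate = 100 * sum(fn) / sum(comparable),
    discordant = data.frame(
      site = sites[disc[, 1]], sample = samples[disc[, 2]],
      type = ifelse(fp[disc], "false_positive", "false_negative"))),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "Concordance over %d sites x %d samples (%d comparable calls):\n",
    x$n_overlap_sites, x$n_overlap_samples, x$n_comparable))
  cat(sprintf("  false positive rate %.3f%%, false negative rate %.3f%%\n",
              x$false_positive_rate, x$false_negative_rate))
  invisible(x)
}

#' Run the simulate -> stats -> ABC pipeline from a configuration
#'
#' Configuration fields: `seed` (root seed), `out_dir`, `models` (model
#' ids), `n_sims`, `n` (sample size), and optional overrides
#' `locus_length_bp`, `n_accept`, `n_keep`, `null_sims`, plus `observed_sfs`
#' (numeric vector; defaults to the first simulated replicate of the first
#' model as a demonstration observation).  Writes reference tables, the
#' diversity table of the simulated pods, ABC posteriors and a JSON
#' manifest recording seeds, settings and output digests.
#'
#' @param config Named list, or path to a YAML/JSON file.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package")
      }
      yaml::read_yaml(config)
    }
  }
  for (f in c("seed", "out_dir", "models", "n_sims", "n")) {
    if (is.null(config[[f]])) stop("config is missing field: ", f)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- default_model_specs(
    locus_length_bp = config$locus_length_bp %||% 3724156L)[config$models]
  if (any(vapply(specs, is.null, logical(1)))) {
    stop("unknown model id in config$models")
  }
  seeds <- derive_seeds(config$seed, length(specs) + 2L)
  stage_log <- list()
  tables <- list()
  for (i in seq_along(specs)) {
    id <- names(specs)[i]
    tables[[id]] <- simulate_batch(specs[[id]], config$n_sims, config$n,
                                   seed = seeds[i])
    f <- file.path(config$out_dir, paste0("ref_", id, ".tsv"))
    write_ref_table(tables[[id]], f)
    stage_log[[paste0("simulate_", id)]] <-
      list(rows = nrow(tables[[id]]), file = f)
  }
  obs <- config$observed_sfs %||%
    as.numeric(tables[[1]][1, grep("^xi_", names(tables[[1]]))])
  if (length(specs) >= 2) {
    fit <- abc_fit(obs, tables, specs,
                   n_accept = config$n_accept %||%
                     max(2L, ceiling(0.1 * config$n_sims)),
                   n_keep = config$n_keep, seed = seeds[length(seeds) - 1L])
    mp <- data.frame(model = names(fit$model_posterior_logistic),
                     p_logistic = as.numeric(fit$model_posterior_logistic),
                     p_rejection = as.numeric(
                       fit$model_posterior_rejection[
                         names(fit$model_posterior_logistic)]))
    mp$p_rejection[is.na(mp$p_rejection)] <- 0
    f <- file.path(config$out_dir, "model_posterior.tsv")
    utils::write.table(mp, f, sep = "\t", quote = FALSE, row.names = FALSE)
    pp <- do.call(rbind, lapply(names(fit$parameters$parameters), function(p) {
      e <- fit$parameters$parameters[[p]]
      data.frame(parameter = p, median = e$median, mode = e$mode,
                 ci_low = e$ci[1], ci_high = e$ci[2], r2 = e$r2)
    }))
    f2 <- file.path(config$out_dir, "parameter_posterior.tsv")
    utils::write.table(pp, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log$abc <- list(best_model = fit$best_model,
                          files = c(f, f2))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("msydemog")),
    seed = config$seed, stage_seeds = seeds,
    settings = config[setdiff(names(config), "out_dir")],
    stages = stage_log,
    digests = as.list(tools::md5sum(
      list.files(config$out_dir, full.names = TRUE, pattern = "\\.tsv$"))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
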