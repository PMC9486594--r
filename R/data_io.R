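#' Read a genotype matrix from CSV or PLINK files
#'
#' Two formats are supported. `csv`: first column sample identifier, one
#' column per marker with a header row of marker identifiers; chromosome
#' and position are parsed from marker identifiers of the form
#' `"<chrom>_<pos>"` or `"<chrom>:<pos>"` when all identifiers match,
#' otherwise markers are placed on chromosome "1" at consecutive positions.
#' `plink`: a bed/bim/fam file set (pass the path prefix or the `.bed`
#' path); dosages are flipped per marker so that they count the minor
#' allele, and missing calls are mean-imputed per marker.
#'
#' @param path file path (CSV) or PLINK prefix.
#' @param format `"auto"` (by extension), `"csv"` or `"plink"`.
#' @return A [genotype_matrix()] object.
#' @export
read_genotype <- function(path, format = c("auto", "csv", "plink")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "plink"
  }
  if (format == "plink") {
    return(read_plink_genotype(path))
  }
  if (!file.exists(path)) data_error(sprintf("genotype file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) data_error("genotype CSV needs a sample column and >= 1 marker")
  ids <- as.character(df[[1L]])
  d <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(d)) data_error("non-numeric dosages in genotype CSV")
  rownames(d) <- ids
  d <- impute_mean(d)
  if (min(d) < -1e-9 || max(d) > 2 + 1e-9) {
    data_error("dosages outside [0, 2] in genotype CSV")
  }
  mk <- colnames(d)
  chrom <- NULL
  pos <- NULL
  hits <- regmatches(mk, regexec("^([A-Za-z0-9]+)[:_]([0-9]+)$", mk))
  if (all(lengths(hits) == 3L)) {
    chrom <- vapply(hits, `[`, "", 2L)
    pos <- as.integer(vapply(hits, `[`, "", 3L))
  }
  genotype_matrix(d, chrom = chrom, pos = pos)
}

#' Write a genotype matrix to CSV
#'
#' Inverse of the CSV reader: first column `sample_id`, one column per
#' marker. Element-wise identical on read-back.
#'
#' @param g a `permlmm_genotype`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(g, path) {
  df <- data.frame(sample_id = rownames(g$dosages), g$dosages,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype vector from CSV
#'
#' The file must have a sample-identifier column (the first) and at least
#' one trait column. Rows with missing values are retained (dropped later
#' during alignment). Replicate measurements for one sample are averaged,
#' with a log message.
#'
#' @param path CSV path.
#' @param trait trait (column) name; defaults to the first trait column.
#' @return Named numeric vector (names = sample identifiers); may contain
#'   `NA`.
#' @export
read_phenotype <- function(path, trait = NULL) {
  if (!file.exists(path)) data_error(sprintf("phenotype file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) {
    data_error("phenotype CSV needs a sample column, a trait column and >= 1 row")
  }
  traits <- colnames(df)[-1L]
  if (is.null(trait)) trait <- traits[1L]
  if (!trait %in% traits) {
    data_error(sprintf(
      "trait '%s' not found; available traits: %s",
      trait, paste(traits, collapse = ", ")
    ))
  }
  ids <- as.character(df[[1L]])
  vals <- suppressWarnings(as.numeric(df[[trait]]))
  if (all(is.na(vals))) data_error("zero parsable phenotype rows")
  if (anyDuplicated(ids)) {
    ndup <- sum(duplicated(ids))
    log_msg("averaging replicate phenotype values for %d duplicated sample id(s)", ndup)
    agg <- tapply(vals, ids, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
    # keep order of first appearance
    first <- ids[!duplicated(ids)]
    vals <- as.numeric(agg[first])
    ids <- first
  }
  setNames(vals, ids)
}

#' Read a covariate matrix from CSV
#'
#' First column sample identifier, remaining columns real-valued covariates
#' (do not include an intercept; it is added internally).
#'
#' @param path CSV path.
#' @return Numeric matrix with sample identifiers as rownames; may contain
#'   `NA` (rows dropped at alignment).
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) data_error(sprintf("covariate file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) data_error("covariate CSV needs a sample column and >= 1 covariate")
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- as.character(df[[1L]])
  x
}

#' Align genotype, phenotype, covariates and kinship to common samples
#'
#' Intersects sample identifiers across all inputs, drops samples with a
#' missing phenotype or covariate value, and imposes a single canonical
#' ordering: the order of appearance in the genotype restricted to the
#' intersection. Requires `n >= c + 2` where `c` is the number of fixed
#' effects (intercept + covariates + marker) so the F-test denominator
#' degrees of freedom stay positive.
#'
#' @param genotype a `permlmm_genotype`.
#' @param phenotype named numeric vector.
#' @param covariates optional numeric matrix with sample rownames.
#' @param kinship `n x n` symmetric matrix with sample dimnames.
#' @return An object of class `permlmm_dataset`: list with `genotype`,
#'   `phenotype`, `covariates` (or `NULL`), `kinship`, `n`, `c`.
#' @export
align_samples <- function(genotype, phenotype, covariates = NULL, kinship) {
  gid <- sample_ids(genotype)
  pid <- names(phenotype)
  if (is.null(pid)) data_error("phenotype must carry sample identifiers")
  kid <- rownames(kinship)
  if (is.null(kid)) data_error("kinship must carry sample identifiers")
  keep <- gid[gid %in% pid & gid %in% kid]
  if (!is.null(covariates)) {
    cid <- rownames(covariates)
    if (is.null(cid)) data_error("covariates must carry sample identifiers")
    keep <- keep[keep %in% cid]
  }
  dropped_inter <- length(gid) - length(keep)
  # drop missing phenotype / covariate values
  ok <- !is.na(phenotype[keep])
  if (!is.null(covariates)) {
    ok <- ok & complete.cases(covariates[keep, , drop = FALSE])
  }
  dropped_na <- sum(!ok)
  keep <- keep[ok]
  n <- length(keep)
  c_fixed <- 2L + if (is.null(covariates)) 0L else ncol(covariates)
  if (n == 0L) data_error("no samples shared across inputs")
  if (n < c_fixed + 2L) {
    data_error(sprintf(
      "only %d aligned samples; need at least %d for %d fixed effects",
      n, c_fixed + 2L, c_fixed
    ))
  }
  if (dropped_inter > 0L || dropped_na > 0L) {
    log_msg("alignment dropped %d sample(s) outside the intersection and %d with missing values; %d retained",
            dropped_inter, dropped_na, n)
  }
  y <- phenotype[keep]
  if (length(unique(y)) < 2L) data_error("aligned phenotype has fewer than 2 distinct values")
  covs <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
  if (!is.null(covs)) {
    if (qr(cbind(1, covs))$rank < 1L + ncol(covs)) {
      data_error("covariates are rank-deficient after alignment")
    }
  }
  ds <- list(
    genotype = genotype[keep, ],
    phenotype = y,
    covariates = covs,
    kinship = kinship[keep, keep],
    n = n,
    c = c_fixed
  )
  class(ds) <- "permlmm_dataset"
  ds
}

#' @export
print.permlmm_dataset <- function(x, ...) {
  cat(sprintf(
    "permlmm dataset: %d samples, %d markers, %d fixed effect(s) incl. intercept and marker\n",
    x$n, ncol(x$genotype$dosages), x$c
  ))
  invisible(x)
}

#' Filter markers on minor allele frequency and count
#'
#' Removes markers whose minor allele frequency is below `maf_min` or whose
#' minor allele count is below `mac_min`. Monomorphic markers are always
#' removed when `maf_min > 0`. Idempotent.
#'
#' @param genotype a `permlmm_genotype`.
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param mac_min minimum minor allele count (non-negative integer).
#' @return Filtered `permlmm_genotype`.
#' @export
filter_maf <- function(genotype, maf_min = 0, mac_min = 0) {
  if (maf_min < 0 || maf_min > 0.5) usage_error("maf_min must lie in [0, 0.5]")
  if (mac_min < 0) usage_error("mac_min must be >= 0")
  d <- genotype$dosages
  n <- nrow(d)
  p <- colMeans(d) / 2
  maf <- pmin(p, 1 - p)
  minor_count <- pmin(colSums(d), 2 * n - colSums(d))
  keep <- maf >= maf_min & minor_count >= mac_min
  if (!any(keep)) data_error("MAF/MAC filter removed all markers")
  if (any(!keep)) {
    log_msg("MAF >= %g / MAC >= %d filter retained %d of %d markers",
            maf_min, as.integer(mac_min), sum(keep), length(keep))
  }
  genotype[, which(keep)]
}

#' Write scan results and a run summary
#'
#' Writes `<prefix>_results.csv` with one row per tested marker (identifier,
#' chromosome, position, MAF, effect estimate, standard error, test
#' statistic, p-value, and adjusted p-values when permutations were run)
#' and `<prefix>_summary.txt` with run-level quantities (n, markers tested,
#' alpha, Bonferroni threshold, permutation threshold and the per-permutation
#' minimal p-values when available, seed).
#'
#' @param fit a [perm_gwas()] result.
#' @param prefix output path prefix; directories are created as needed.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(fit, prefix) {
  stopifnot(inherits(fit, "perm_gwas"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  res_path <- paste0(prefix, "_results.csv")
  sum_path <- paste0(prefix, "_summary.txt")
  ok <- tryCatch({
    write.csv(fit$scan, res_path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) data_error(sprintf("cannot write results to %s", res_path))
  th <- fit$thresholds
  lines <- c(
    sprintf("n_samples: %d", fit$n),
    sprintf("m_tested: %d", th$m),
    sprintf("alpha: %.17g", th$alpha),
    sprintf("bonferroni_threshold: %.17g", th$bonferroni),
    sprintf("sigma_g2: %.17g", fit$vc$sigma_g2),
    sprintf("sigma_e2: %.17g", fit$vc$sigma_e2),
    sprintf("seed: %d", as.integer(fit$seed))
  )
  if (!is.null(th$maxt)) {
    lines <- c(
      lines,
      sprintf("q_permutations: %d", length(th$p_min)),
      sprintf("maxt_threshold: %.17g", th$maxt),
      sprintf("p_min: %s", paste(sprintf("%.17g", th$p_min), collapse = ","))
    )
  }
  writeLines(lines, sum_path)
  invisible(c(results = res_path, summary = sum_path))
}
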