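#' Permutation-based linear mixed model GWAS
#'
#' Fits the LMM association scan and, when `q > 0`, the Westfall-Young maxT
#' permutation procedure. The pipeline is: align samples (unless an aligned
#' dataset is supplied), filter markers on minor allele frequency/count,
#' compute the realized-relationship kinship if none is given, estimate
#' null-model variance components, scan all markers batch-wise, then run
#' `q` phenotype permutations (variance components re-estimated per
#' permutation) and derive the Bonferroni and maxT thresholds.
#'
#' @param genotype a `permlmm_genotype`, or an aligned `permlmm_dataset`
#'   (in which case `phenotype`, `covariates`, `kinship`, `maf_min`,
#'   `mac_min` are ignored).
#' @param phenotype named numeric vector.
#' @param covariates optional numeric matrix with sample rownames
#'   (intercept excluded; added internally).
#' @param kinship optional precomputed kinship matrix; computed from the
#'   filtered markers via [realized_relationship()] when `NULL`.
#' @param maf_min,mac_min marker filters applied before scanning.
#' @param alpha target family-wise error rate.
#' @param q number of phenotype permutations; `0` disables the permutation
#'   threshold and the scan degrades to a plain batched LMM GWAS.
#' @param seed RNG seed for the permutation stream.
#' @param batch_size markers per batch (results do not depend on it).
#' @param method variance-component criterion, `"ML"` or `"REML"`.
#' @param backend `"batch"` or `"naive"` (reference implementation).
#' @return Object of class `perm_gwas`: list with
#'   \describe{
#'     \item{scan}{data.frame per tested marker: `marker_id`, `chrom`,
#'       `pos`, `maf`, `effect`, `se`, `statistic`, `pvalue`, and when
#'       `q > 0` `p_adj_maxt` (Westfall-Young adjusted).}
#'     \item{thresholds}{list: `alpha`, `m`, `bonferroni`, and when `q > 0`
#'       `maxt` and the per-permutation minimal p-values `p_min`.}
#'     \item{vc}{null-model variance components.}
#'     \item{perm}{the `permutation_scan` (or `NULL`).}
#'     \item{n, c, seed, call}{bookkeeping.}
#'   }
#' @examples
#' g <- simulate_genotypes(n = 60, m = 120, seed = 7)
#' ph <- simulate_phenotype(g, simulation_config(n_background = 50, seed = 7))
#' fit <- perm_gwas(g, ph$values, q = 20, seed = 7)
#' summary(fit)
#' @export
perm_gwas <- function(genotype, phenotype = NULL, covariates = NULL,
                      kinship = NULL, maf_min = 0, mac_min = 0,
                      alpha = 0.05, q = 0L, seed = 42L,
                      batch_size = 5000L, method = c("ML", "REML"),
                      backend = c("batch", "naive")) {
  method <- match.arg(method)
  backend <- match.arg(backend)
  if (alpha <= 0 || alpha >= 1) usage_error("alpha must lie in (0, 1)")
  if (q < 0) usage_error("q must be >= 0")
  if (inherits(genotype, "permlmm_dataset")) {
    ds <- genotype
  } else {
    g <- filter_maf(genotype, maf_min = maf_min, mac_min = mac_min)
    if (is.null(kinship)) {
      # centering frequencies come from the analysis samples, so restrict
      # to the usable sample set before estimating kinship
      ids <- sample_ids(g)
      ids <- ids[ids %in% names(phenotype)[!is.na(phenotype)]]
      if (!is.null(covariates)) {
        cid <- rownames(covariates)[complete.cases(covariates)]
        ids <- ids[ids %in% cid]
      }
      if (length(ids) < 3L) data_error("too few usable samples to estimate kinship")
      kinship <- stabilize_kinship(realized_relationship(g[ids, ]))
    }
    ds <- align_samples(g, phenotype, covariates = covariates, kinship = kinship)
  }
  scan <- gwas_scan(ds, batch_size = batch_size, method = method,
                    backend = backend)
  m_tested <- sum(!scan$flagged)
  thresholds <- list(
    alpha = alpha,
    m = m_tested,
    bonferroni = bonferroni_threshold(alpha, m_tested)
  )
  perm <- NULL
  tab <- scan$table
  if (q > 0) {
    perms <- generate_permutations(ds$n, q, seed)
    perm <- permutation_scan(ds, perms, batch_size = batch_size,
                             method = method)
    thresholds$p_min <- perm$p_min[!perm$failed]
    thresholds$maxt <- maxt_threshold(thresholds$p_min, alpha)
    tab$p_adj_maxt <- westfall_young_adjusted(perm$t_max, tab$statistic)
  }
  out <- list(
    scan = tab,
    thresholds = thresholds,
    vc = scan$vc,
    perm = perm,
    n = ds$n,
    c = scan$c,
    seed = as.integer(seed),
    call = match.call()
  )
  class(out) <- "perm_gwas"
  out
}

#' @export
print.perm_gwas <- function(x, ...) {
  th <- x$thresholds
  cat("Permutation-based LMM GWAS\n")
  cat(sprintf("  samples: %d, markers tested: %d, fixed effects: %d\n",
              x$n, th$m, x$c))
  cat(sprintf("  sigma_g2 = %.4g, sigma_e2 = %.4g (h2 = %.3f)\n",
              x$vc$sigma_g2, x$vc$sigma_e2,
              x$vc$sigma_g2 / (x$vc$sigma_g2 + x$vc$sigma_e2)))
  cat(sprintf("  Bonferroni threshold (alpha = %g): %.3g\n",
              th$alpha, th$bonferroni))
  if (!is.null(th$maxt)) {
    cat(sprintf("  maxT permutation threshold (q = %d): %.3g\n",
                length(th$p_min), th$maxt))
  }
  invisible(x)
}

#' @export
summary.perm_gwas <- function(object, n_top = 10L, ...) {
  th <- object$thresholds
  tab <- object$scan
  sig_bonf <- sum(!is.na(tab$pvalue) & tab$pvalue < th$bonferroni)
  sig_maxt <- if (!is.null(th$maxt)) {
    sum(!is.na(tab$pvalue) & tab$pvalue < th$maxt)
  } else NA_integer_
  top <- tab[order(tab$pvalue), , drop = FALSE]
  top <- head(top[!is.na(top$pvalue), , drop = FALSE], n_top)
  out <- list(
    fit = object,
    top = top,
    n_significant = c(bonferroni = sig_bonf, maxt = sig_maxt)
  )
  class(out) <- "summary.perm_gwas"
  out
}

#' @export
print.summary.perm_gwas <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  significant markers: %d (Bonferroni)%s\n",
              x$n_significant[["bonferroni"]],
              if (!is.na(x$n_significant[["maxt"]])) {
                sprintf(", %d (maxT)", x$n_significant[["maxt"]])
              } else ""))
  cat("\nTop associations:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.perm_gwas <- function(object, ...) {
  setNames(object$scan$effect, object$scan$marker_id)
}

#' Manhattan plot of a scan
#'
#' Plots `-log10(p)` against cumulative genomic position with the
#' Bonferroni (red, dashed) and, if available, maxT (blue) thresholds.
#'
#' @param x a `perm_gwas` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.perm_gwas <- function(x, ...) {
  tab <- x$scan[!is.na(x$scan$pvalue), , drop = FALSE]
  chroms <- unique(tab$chrom)
  offs <- setNames(numeric(length(chroms)), chroms)
  run <- 0
  for (ch in chroms) {
    offs[ch] <- run
    run <- run + max(tab$pos[tab$chrom == ch]) + 1
  }
  xpos <- tab$pos + offs[tab$chrom]
  col <- (match(tab$chrom, chroms) %% 2L) + 1L
  plot(xpos, -log10(tab$pvalue), pch = 20, col = c("grey30", "grey60")[col],
       xlab = "cumulative position (bp)", ylab = expression(-log[10](p)),
       ...)
  abline(h = -log10(x$thresholds$bonferroni), col = "red", lty = 2)
  if (!is.null(x$thresholds$maxt)) {
    abline(h = -log10(x$thresholds$maxt), col = "blue")
  }
  invisible(x)
}
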