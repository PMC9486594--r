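# Chunked scanning from PLINK .bed files.
#
# .bed is SNP-major, so marker chunks are contiguous reads; with a
# precomputed kinship the full dosage matrix never has to be resident.
# Whitening factors (observed + per permutation) are prepared once from
# phenotype, covariates and kinship, then each marker chunk is read,
# filtered, whitened and regressed.

#' Chunked permutation GWAS from a PLINK file set
#'
#' Streaming variant of [perm_gwas()]: markers are read from the `.bed`
#' file `chunk_size` at a time. Requires a precomputed kinship (the
#' realized-relationship estimator needs the full matrix). Allele
#' frequencies for the MAF/MAC filter are computed on the aligned analysis
#' samples. Results are identical to the in-memory scan on the same
#' aligned samples.
#'
#' @param prefix PLINK path prefix (or `.bed` path).
#' @param phenotype named numeric vector.
#' @param covariates optional numeric matrix with sample rownames.
#' @param kinship precomputed kinship matrix with sample dimnames.
#' @param maf_min,mac_min marker filters.
#' @param alpha target FWER.
#' @param q permutations (0 = none).
#' @param seed permutation seed.
#' @param chunk_size markers per read.
#' @param batch_size markers per regression batch.
#' @param method variance-component criterion.
#' @return A `perm_gwas` object (the `perm` element carries per-permutation
#'   `t_max`/`p_min` and variance components but not the full statistic
#'   matrix).
#' @export
perm_gwas_chunked <- function(prefix, phenotype, covariates = NULL, kinship,
                              maf_min = 0, mac_min = 0, alpha = 0.05,
                              q = 0L, seed = 42L, chunk_size = 10000L,
                              batch_size = 5000L, method = c("ML", "REML")) {
  method <- match.arg(method)
  if (chunk_size < 1L) usage_error("chunk_size must be >= 1")
  p <- plink_paths(prefix)
  fam_ids <- read_fam(p$fam)
  bim <- read_bim(p$bim)
  n_all <- length(fam_ids)
  m_all <- nrow(bim)

  keep <- fam_ids[fam_ids %in% names(phenotype) & fam_ids %in% rownames(kinship)]
  if (!is.null(covariates)) keep <- keep[keep %in% rownames(covariates)]
  keep <- keep[!is.na(phenotype[keep])]
  if (!is.null(covariates)) {
    keep <- keep[complete.cases(covariates[keep, , drop = FALSE])]
  }
  n <- length(keep)
  c0 <- 1L + if (is.null(covariates)) 0L else ncol(covariates)
  if (n < c0 + 3L) data_error("too few aligned samples for the chunked scan")
  row_idx <- match(keep, fam_ids)
  y <- as.numeric(phenotype[keep])
  X0 <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) X0 <- cbind(X0, covariates[keep, , drop = FALSE])
  K <- kinship[keep, keep]
  cdf <- c0 + 1L

  eigK <- eigen(K, symmetric = TRUE)
  vc <- estimate_variance_components(y, X0, K, method = method, eigen_K = eigK)
  cm <- covariance_model(vc, K)
  yw <- as.numeric(whiten(cm, y))
  X0w <- whiten(cm, X0)

  perms <- NULL
  perm_white <- list()
  if (q > 0) {
    perms <- generate_permutations(n, q, seed)
    P <- unclass(perms)
    perm_white <- lapply(seq_len(q), function(k) {
      yk <- y[P[k, ]]
      vck <- estimate_variance_components(yk, X0, K, method = method,
                                          eigen_K = eigK)
      cmk <- covariance_model(vck, K)
      list(vc = vck, C = cmk$C,
           yw = as.numeric(whiten(cmk, yk)), X0w = whiten(cmk, X0))
    })
  }

  kept_marker <- logical(m_all)
  maf_all <- rep(NA_real_, m_all)
  effect <- se <- stat <- pval <- rep(NA_real_, m_all)
  perm_stat <- if (q > 0) matrix(NA_real_, q, m_all) else NULL

  for (j0 in seq(1L, m_all, by = chunk_size)) {
    j1 <- min(j0 + chunk_size - 1L, m_all)
    d <- read_bed_dosages(p$bed, n_all, m_all, j0:j1)
    d <- d[row_idx, , drop = FALSE]
    d <- flip_to_minor(d)
    d <- impute_mean(d)
    pfreq <- colMeans(d) / 2
    maf <- pmin(pfreq, 1 - pfreq)
    mac <- pmin(colSums(d), 2 * n - colSums(d))
    ok <- maf >= maf_min & mac >= mac_min
    idx <- (j0:j1)[ok]
    maf_all[j0:j1] <- maf
    if (!length(idx)) next
    kept_marker[idx] <- TRUE
    d <- d[, ok, drop = FALSE]
    for (b0 in seq(1L, ncol(d), by = batch_size)) {
      b1 <- min(b0 + batch_size - 1L, ncol(d))
      cols <- idx[b0:b1]
      Mb <- d[, b0:b1, drop = FALSE]
      Mw <- whiten(cm, Mb)
      fit <- batch_ols(X0w, Mw, yw)
      effect[cols] <- fit$effect
      se[cols] <- fit$se
      st <- f_statistic(fit$rss0, fit$rss, n, cdf)
      st[fit$flagged] <- NA_real_
      stat[cols] <- st
      pval[cols] <- ifelse(fit$flagged, NA_real_, f_pvalue(st, n, cdf))
      if (q > 0) {
        for (k in seq_len(q)) {
          pw <- perm_white[[k]]
          Mwk <- forwardsolve(pw$C, Mb)
          fk <- batch_ols(pw$X0w, Mwk, pw$yw)
          stk <- f_statistic(fk$rss0, fk$rss, n, cdf)
          stk[fk$flagged] <- NA_real_
          perm_stat[k, cols] <- stk
        }
      }
    }
  }
  if (!any(kept_marker & !is.na(stat))) data_error("no markers tested")

  tested <- which(kept_marker)
  tab <- data.frame(
    marker_id = bim$marker_id[tested],
    chrom = as.character(bim$chrom[tested]),
    pos = bim$pos[tested],
    maf = maf_all[tested],
    effect = effect[tested],
    se = se[tested],
    statistic = stat[tested],
    pvalue = pval[tested],
    stringsAsFactors = FALSE
  )
  m_tested <- sum(!is.na(tab$statistic))
  thresholds <- list(alpha = alpha, m = m_tested,
                     bonferroni = bonferroni_threshold(alpha, m_tested))
  perm <- NULL
  if (q > 0) {
    t_max <- apply(perm_stat[, tested, drop = FALSE], 1L, max, na.rm = TRUE)
    p_min <- f_pvalue(t_max, n, cdf)
    thresholds$p_min <- p_min
    thresholds$maxt <- maxt_threshold(p_min, alpha)
    tab$p_adj_maxt <- westfall_young_adjusted(t_max, tab$statistic)
    perm <- list(
      statistic = NULL,
      vc = data.frame(
        sigma_g2 = vapply(perm_white, function(w) w$vc$sigma_g2, 0),
        sigma_e2 = vapply(perm_white, function(w) w$vc$sigma_e2, 0)
      ),
      t_max = t_max, p_min = p_min,
      failed = rep(FALSE, q), n = n, c = cdf, seed = as.integer(seed)
    )
    class(perm) <- "permutation_scan"
  }
  out <- list(scan = tab, thresholds = thresholds, vc = vc, perm = perm,
              n = n, c = cdf, seed = as.integer(seed), call = match.call())
  class(out) <- "perm_gwas"
  out
}
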