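# Westfall-Young maxT permutation machinery.
#
# The phenotype is permuted q times against fixed genotype, covariates and
# kinship; variance components are re-estimated for every permuted
# phenotype (the permuted trait carries no genetic signal, so its
# covariance model differs from the observed one), the data are whitened
# with the permutation-specific Cholesky factor, and all markers are
# scanned. The per-permutation maximal statistics / minimal p-values yield
# an FWER-controlling significance threshold.

#' Generate seeded phenotype permutations
#'
#' `q` independent uniform random permutations of `1..n` from a seeded
#' generator; the full set is materialized up front so downstream batching
#' choices cannot change the permutation stream.
#'
#' @param n number of samples (>= 2).
#' @param q number of permutations (>= 1).
#' @param seed RNG seed.
#' @return Object of class `permutation_set`: `q x n` integer matrix with
#'   attributes `n`, `q`, `seed`.
#' @export
generate_permutations <- function(n, q, seed) {
  if (n < 2L) usage_error("need n >= 2 to permute")
  if (q < 1L) usage_error("need q >= 1 permutations")
  P <- with_seed(seed, {
    t(vapply(seq_len(q), function(k) sample.int(n), integer(n)))
  })
  attr(P, "n") <- as.integer(n)
  attr(P, "q") <- as.integer(q)
  attr(P, "seed") <- as.integer(seed)
  class(P) <- c("permutation_set", class(P))
  P
}

#' Permutation-batched LMM scan
#'
#' For each permutation of the phenotype: re-estimates variance components
#' on the permuted null model (reusing one eigendecomposition of `K`),
#' whitens with the permutation-specific Cholesky factor, and computes the
#' F statistics of all markers. Covariate columns are not permuted.
#' Permutations whose variance-component optimization fails are flagged and
#' excluded from the maxima, with a warning.
#'
#' @param dataset an aligned dataset from [align_samples()].
#' @param permutations a [generate_permutations()] set (columns must match
#'   `dataset$n`).
#' @param batch_size markers per batch.
#' @param method variance-component criterion.
#' @return Object of class `permutation_scan`: list with `statistic`
#'   (`q x m`), `vc` (data.frame of per-permutation `sigma_g2`, `sigma_e2`),
#'   `t_max`, `p_min`, `failed` (logical per permutation), `n`, `c`, `seed`.
#' @export
permutation_scan <- function(dataset, permutations, batch_size = 5000L,
                             method = c("ML", "REML")) {
  stopifnot(inherits(dataset, "permlmm_dataset"))
  method <- match.arg(method)
  P <- unclass(permutations)
  if (ncol(P) != dataset$n) data_error("permutation length does not match sample count")
  q <- nrow(P)
  X0 <- null_design(dataset)
  y <- as.numeric(dataset$phenotype)
  K <- dataset$kinship
  M <- dataset$genotype$dosages
  m <- ncol(M)
  eigK <- eigen(K, symmetric = TRUE)
  stat <- matrix(NA_real_, q, m)
  sg2 <- se2 <- rep(NA_real_, q)
  failed <- logical(q)
  cdf <- ncol(X0) + 1L
  for (k in seq_len(q)) {
    yk <- y[P[k, ]]
    res <- tryCatch({
      vck <- estimate_variance_components(yk, X0, K, method = method,
                                          eigen_K = eigK)
      sc <- scan_core(yk, X0, M, K, vck, batch_size = batch_size)
      list(vc = vck, stat = sc$statistic, flagged = sc$flagged)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed[k] <- TRUE
      next
    }
    st <- res$stat
    st[res$flagged] <- NA_real_
    stat[k, ] <- st
    sg2[k] <- res$vc$sigma_g2
    se2[k] <- res$vc$sigma_e2
  }
  if (any(failed)) {
    warning(sprintf(
      "%d of %d permutations failed variance-component estimation and are excluded",
      sum(failed), q
    ))
  }
  ok <- !failed
  t_max <- rep(NA_real_, q)
  t_max[ok] <- apply(stat[ok, , drop = FALSE], 1L, max, na.rm = TRUE)
  p_min <- f_pvalue(t_max, dataset$n, cdf)
  out <- list(
    statistic = stat,
    vc = data.frame(sigma_g2 = sg2, sigma_e2 = se2),
    t_max = t_max,
    p_min = p_min,
    failed = failed,
    n = dataset$n,
    c = cdf,
    seed = attr(permutations, "seed")
  )
  class(out) <- "permutation_scan"
  out
}

#' @export
print.permutation_scan <- function(x, ...) {
  cat(sprintf(
    "permlmm permutation scan: q = %d permutations x %d markers (%d failed)\n",
    nrow(x$statistic), ncol(x$statistic), sum(x$failed)
  ))
  invisible(x)
}

#' maxT permutation significance threshold
#'
#' The alpha-th percentile of the per-permutation minimal p-values,
#' realized as the `k`-th smallest value with `k = max(1, floor(alpha * q))`.
#' Declaring significance by `p < delta_star` (strict) then controls the
#' family-wise error rate at `alpha` whenever `alpha * q >= 1`, and degrades
#' conservatively (k clamped to 1) for very small `q`.
#'
#' @param p_min per-permutation minimal p-values (in `(0, 1]`; `NA`s from
#'   failed permutations are dropped).
#' @param alpha target FWER in `(0, 1)`.
#' @return The threshold `delta_star`.
#' @export
maxt_threshold <- function(p_min, alpha = 0.05) {
  p_min <- p_min[!is.na(p_min)]
  if (length(p_min) == 0L) usage_error("empty p_min list")
  if (alpha <= 0 || alpha >= 1) usage_error("alpha must lie in (0, 1)")
  k <- max(1L, floor(alpha * length(p_min)))
  sort(p_min)[k]
}

#' Westfall-Young adjusted p-values
#'
#' For each marker, the fraction of permutations whose maximal statistic is
#' at least the observed statistic:
#' `p_tilde_j = #\{k : t_max^(k) >= t_j\} / q`.
#'
#' @param t_max per-permutation maximal statistics (`NA`s dropped).
#' @param statistic observed per-marker statistics.
#' @return Adjusted p-values in `[0, 1]` (`NA` for `NA` statistics).
#' @export
westfall_young_adjusted <- function(t_max, statistic) {
  t_max <- t_max[!is.na(t_max)]
  if (length(t_max) == 0L) usage_error("empty t_max list")
  st <- sort(t_max)
  q <- length(st)
  out <- rep(NA_real_, length(statistic))
  ok <- !is.na(statistic)
  # count t_max >= t  =  q - #(t_max < t)
  out[ok] <- (q - findInterval(statistic[ok], st, left.open = TRUE)) / q
  out
}

#' Pooled permutation-adjusted p-values
#'
#' Pools all `q x m` permuted statistics into one empirical null and sets
#' `p_j = #\{(k, j') : t^(k)_{j'} >= t_j\} / (q m)`. Flagged (`NA`) permuted
#' statistics are excluded from the pool and its denominator. The raw
#' count/(qm) estimator is used by default; `smoothing = TRUE` applies
#' add-one smoothing `(count + 1) / (qm + 1)` so p-values are bounded away
#' from zero.
#'
#' @param perm_stat `q x m` matrix of permuted statistics.
#' @param statistic observed per-marker statistics.
#' @param smoothing logical; default `FALSE`.
#' @return Pooled p-values, monotone non-increasing in the statistic.
#' @export
pooled_adjusted_pvalues <- function(perm_stat, statistic, smoothing = FALSE) {
  pool <- sort(perm_stat[!is.na(perm_stat)])
  N <- length(pool)
  if (N == 0L) usage_error("empty permutation pool")
  out <- rep(NA_real_, length(statistic))
  ok <- !is.na(statistic)
  cnt <- N - findInterval(statistic[ok], pool, left.open = TRUE)
  out[ok] <- if (smoothing) (cnt + 1) / (N + 1) else cnt / N
  out
}

#' Bonferroni significance threshold
#'
#' `alpha / m`, with `m` the number of markers actually tested (after
#' filtering and excluding flagged markers).
#'
#' @param alpha target FWER.
#' @param m number of tests (>= 1).
#' @return The threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1L) usage_error("need m >= 1 tests")
  alpha / m
}
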