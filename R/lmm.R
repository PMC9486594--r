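# Linear mixed model core.
#
# Model per marker: y = X beta + u + eps with u ~ N(0, sigma_g2 * K),
# eps ~ N(0, sigma_e2 * I). Variance components are estimated once on the
# null model (intercept + covariates, no marker) and reused for every
# marker's alternative model. The generalized least squares problem is
# turned into ordinary least squares by whitening with the inverse Cholesky
# factor of V = sigma_g2 * K + sigma_e2 * I, and marker regressions are
# evaluated batch-wise through shared cross-products.

#' Estimate variance components of the null LMM
#'
#' Maximizes the (restricted) likelihood of
#' `y ~ N(X beta, sigma_g2 * K + sigma_e2 * I)` by profiling out `beta` and
#' the total scale analytically after a single eigendecomposition of `K`,
#' leaving a one-dimensional optimization over the variance ratio
#' `delta = sigma_e2 / sigma_g2`. The profile is evaluated on a dense log
#' grid (101 points over `[1e-5, 1e5]`) and refined locally with
#' [stats::optimize()].
#'
#' @param y numeric phenotype vector (no missing values).
#' @param X null-model design matrix (intercept + covariates, no marker);
#'   `NULL` means intercept only.
#' @param K kinship matrix.
#' @param method `"ML"` (default) or `"REML"`.
#' @param eigen_K optional precomputed `eigen(K, symmetric = TRUE)`; pass it
#'   when calling repeatedly with the same `K` (e.g. across permutations).
#' @param n_grid number of log-grid points.
#' @return Object of class `variance_components`: list with `sigma_g2`,
#'   `sigma_e2`, `delta`, `log_likelihood` (value of the maximized
#'   criterion), `method`.
#' @export
estimate_variance_components <- function(y, X = NULL, K, method = c("ML", "REML"),
                                         eigen_K = NULL, n_grid = 101L) {
  method <- match.arg(method)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != n) data_error("null design and phenotype dimensions differ")
  if (var(y) == 0) data_error("phenotype has zero variance")
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n) {
    data_error("kinship dimensions do not match the phenotype")
  }
  if (is.null(eigen_K)) eigen_K <- eigen(K, symmetric = TRUE)
  S <- pmax(eigen_K$values, 0)
  U <- eigen_K$vectors
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)
  p <- ncol(X)

  # profile negative log-likelihood in log(delta)
  nll <- function(ldelta) {
    w <- S + exp(ldelta)
    sw <- sqrt(w)
    Xw <- Xr / sw
    yw <- yr / sw
    fit <- qr(Xw)
    if (fit$rank < p) return(Inf)
    res <- qr.resid(fit, yw)
    rss <- sum(res^2)
    if (method == "ML") {
      s2 <- rss / n
      0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(w)) + n)
    } else {
      s2 <- rss / (n - p)
      XtX <- crossprod(Xw)
      0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + sum(log(w)) +
               determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
    }
  }

  grid <- seq(log(1e-5), log(1e5), length.out = n_grid)
  vals <- vapply(grid, nll, 0)
  if (all(!is.finite(vals))) numeric_error("variance-component profile is degenerate")
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- if (lo < hi) optimize(nll, c(lo, hi), tol = 1e-6) else
    list(minimum = grid[i], objective = vals[i])
  ldelta <- opt$minimum
  delta <- exp(ldelta)

  w <- S + delta
  sw <- sqrt(w)
  fit <- qr(Xr / sw)
  rss <- sum(qr.resid(fit, yr / sw)^2)
  sigma_g2 <- if (method == "ML") rss / n else rss / (n - p)
  sigma_e2 <- delta * sigma_g2
  out <- list(
    sigma_g2 = sigma_g2,
    sigma_e2 = sigma_e2,
    delta = delta,
    log_likelihood = -opt$objective,
    method = method
  )
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  h2 <- x$sigma_g2 / (x$sigma_g2 + x$sigma_e2)
  cat(sprintf(
    "variance components (%s): sigma_g2 = %.4g, sigma_e2 = %.4g (h2 = %.3f), logLik = %.4f\n",
    x$method, x$sigma_g2, x$sigma_e2, h2, x$log_likelihood
  ))
  invisible(x)
}

#' Covariance model of the null LMM
#'
#' Assembles `V = sigma_g2 * K + sigma_e2 * I` and its lower-triangular
#' Cholesky factor `C` with `V = C C'`.
#'
#' @param vc a `variance_components` object (or list with `sigma_g2`,
#'   `sigma_e2`).
#' @param K kinship matrix.
#' @return Object of class `covariance_model`: list with `V` and `C`.
#' @export
covariance_model <- function(vc, K) {
  V <- vc$sigma_g2 * K + diag(vc$sigma_e2, nrow(K))
  ch <- try(chol(V), silent = TRUE)
  if (inherits(ch, "try-error")) {
    numeric_error("V = sigma_g2*K + sigma_e2*I is not positive definite")
  }
  out <- list(V = V, C = t(ch))
  class(out) <- "covariance_model"
  out
}

#' Whiten data with the inverse Cholesky factor
#'
#' Computes `C^{-1} x` by triangular forward-substitution (no explicit
#' inverse), where `V = C C'`. Applied to the phenotype and to every design
#' block of a batch, this turns generalized least squares under `V` into
#' ordinary least squares.
#'
#' @param model a `covariance_model` (or a lower-triangular matrix `C`).
#' @param x vector or matrix with `n` rows.
#' @return Whitened copy of `x`.
#' @export
whiten <- function(model, x) {
  C <- if (inherits(model, "covariance_model")) model$C else model
  if (NROW(x) != nrow(C)) data_error("dimension mismatch in whiten()")
  forwardsolve(C, x)
}

#' Batched ordinary least squares over marker design blocks
#'
#' Every block shares the whitened base design (intercept + covariates) and
#' differs only in its marker column, so the per-block normal equations are
#' solved simultaneously from shared cross-products. Returns the null-model
#' residual sum of squares, and per marker the full coefficient vector,
#' residual sum of squares, marker effect and standard error. A marker
#' column collinear with the base design (e.g. monomorphic) yields flagged
#' `NA` results rather than an error.
#'
#' @param base whitened `n x c0` base design matrix.
#' @param markers whitened `n x b` matrix of marker columns (one block per
#'   column); `NULL` fits the null model only.
#' @param y whitened phenotype vector.
#' @return List with `rss0`, and vectors/matrices over the batch:
#'   `coefficients` (`(c0+1) x b`), `rss`, `effect`, `se`, `flagged`.
#' @export
batch_ols <- function(base, markers, y) {
  base <- as.matrix(base)
  n <- nrow(base)
  c0 <- ncol(base)
  A <- crossprod(base)
  cA <- try(chol(A), silent = TRUE)
  if (inherits(cA, "try-error")) data_error("base design is rank-deficient")
  v <- crossprod(base, y)
  beta_base <- backsolve(cA, forwardsolve(t(cA), v)) # A^{-1} v
  # residualize against the base design and work with residual
  # cross-products: avoids the large-minus-large cancellation of the raw
  # normal equations when the whitened scale is ill-conditioned
  r_y <- y - as.numeric(base %*% beta_base)
  rss0 <- sum(r_y^2)
  if (is.null(markers)) {
    return(list(rss0 = rss0, coefficients = beta_base, rss = numeric(0),
                effect = numeric(0), se = numeric(0), flagged = logical(0)))
  }
  markers <- as.matrix(markers)
  if (nrow(markers) != n || length(y) != n) data_error("dimension mismatch in batch_ols()")
  b <- ncol(markers)
  cdf <- c0 + 1L # fixed effects per block
  Umat <- crossprod(base, markers)                     # c0 x b
  AiU <- backsolve(cA, forwardsolve(t(cA), Umat))      # A^{-1} U
  R_M <- markers - base %*% AiU                        # marker residuals
  s <- colSums(markers^2)
  g <- colSums(R_M^2)                                  # marker SS after projection
  flag <- !(g > 1e-10 * pmax(s, 1))
  g_safe <- ifelse(flag, NA_real_, g)
  effect <- as.numeric(crossprod(R_M, r_y)) / g_safe
  rss <- pmax(rss0 - effect^2 * g_safe, 0)
  dof <- n - cdf
  if (dof <= 0) data_error("non-positive degrees of freedom (n <= c)")
  se <- sqrt(rss / dof / g_safe)
  coefs <- rbind(
    matrix(beta_base, c0, b) - AiU * rep(effect, each = c0),
    effect
  )
  rownames(coefs) <- c(colnames(base) %||% paste0("x", seq_len(c0)), "marker")
  list(rss0 = rss0, coefficients = coefs, rss = as.numeric(rss),
       effect = as.numeric(effect), se = as.numeric(se), flagged = flag)
}

#' F statistic for one extra regressor
#'
#' `t = (n - c) * (RSS0 - RSS) / RSS`, comparing the null model (RSS0) to
#' the alternative including the marker (RSS), with `c` fixed effects in the
#' alternative. Small negative values from floating-point cancellation are
#' clipped to 0; a saturated fit (`RSS = 0`) yields `Inf`.
#'
#' @param rss0 null residual sum of squares (scalar or vector).
#' @param rss alternative residual sums of squares.
#' @param n sample count.
#' @param c number of fixed effects in the alternative model.
#' @return Numeric vector of statistics (`NA` passed through).
#' @export
f_statistic <- function(rss0, rss, n, c) {
  if (n <= c) usage_error("f_statistic requires n > c")
  t <- (n - c) * (rss0 - rss) / rss
  t[!is.na(rss) & rss == 0] <- Inf
  pmax(t, 0)
}

#' Upper-tail F-test p-value
#'
#' Survival probability of the F distribution with `(1, n - c)` degrees of
#' freedom.
#'
#' @inheritParams f_statistic
#' @param t statistic(s), non-negative.
#' @return p-values in `[0, 1]`.
#' @export
f_pvalue <- function(t, n, c) {
  if (n <= c) usage_error("f_pvalue requires n > c")
  pf(t, 1, n - c, lower.tail = FALSE)
}

# Core scan of all markers for one phenotype under given variance
# components. Shared by gwas_scan() and permutation_scan() so an identity
# permutation reproduces the observed scan bit-for-bit.
scan_core <- function(y, X0, M, K, vc, batch_size = 5000L) {
  n <- length(y)
  cdf <- ncol(X0) + 1L
  cm <- covariance_model(vc, K)
  yw <- as.numeric(whiten(cm, y))
  X0w <- whiten(cm, X0)
  # whiten all markers in one triangular solve: keeps results independent
  # of the regression batch size (a batched solve would re-block the
  # triangular solve and perturb near-singular V cases at round-off level)
  Mw_all <- whiten(cm, M)
  m <- ncol(M)
  stat <- beta <- se <- rss <- rep(NA_real_, m)
  rss0 <- NA_real_
  flagged <- logical(m)
  for (j0 in seq(1L, m, by = batch_size)) {
    j1 <- min(j0 + batch_size - 1L, m)
    Mw <- Mw_all[, j0:j1, drop = FALSE]
    fit <- batch_ols(X0w, Mw, yw)
    rss0 <- fit$rss0
    idx <- j0:j1
    beta[idx] <- fit$effect
    se[idx] <- fit$se
    rss[idx] <- fit$rss
    flagged[idx] <- fit$flagged
    stat[idx] <- f_statistic(fit$rss0, fit$rss, n, cdf)
  }
  pval <- rep(NA_real_, m)
  ok <- !flagged
  pval[ok] <- f_pvalue(stat[ok], n, cdf)
  list(statistic = stat, pvalue = pval, effect = beta, se = se,
       rss = rss, rss0 = rss0, flagged = flagged, n = n, c = cdf)
}

# Reference scan: per-marker generalized least squares with explicit dense
# V solves (no whitening, no batching). Slow; used as an independent
# cross-check of the batched route.
scan_naive <- function(y, X0, M, K, vc) {
  n <- length(y)
  V <- vc$sigma_g2 * K + diag(vc$sigma_e2, n)
  Vi <- chol2inv(chol(V))
  cdf <- ncol(X0) + 1L
  gls_rss <- function(X) {
    XtVi <- crossprod(X, Vi)
    b <- solve(XtVi %*% X, XtVi %*% y)
    r <- y - X %*% b
    list(beta = b, rss = as.numeric(crossprod(r, Vi %*% r)))
  }
  null <- gls_rss(X0)
  m <- ncol(M)
  stat <- beta <- se <- rep(NA_real_, m)
  flagged <- logical(m)
  for (j in seq_len(m)) {
    X <- cbind(X0, M[, j])
    r <- qr(X)$rank
    if (r < cdf) {
      flagged[j] <- TRUE
      next
    }
    fit <- gls_rss(X)
    stat[j] <- max((n - cdf) * (null$rss - fit$rss) / fit$rss, 0)
    beta[j] <- fit$beta[cdf]
    XtViX_inv <- solve(crossprod(X, Vi %*% X))
    se[j] <- sqrt(fit$rss / (n - cdf) * XtViX_inv[cdf, cdf])
  }
  pval <- rep(NA_real_, m)
  pval[!flagged] <- f_pvalue(stat[!flagged], n, cdf)
  list(statistic = stat, pvalue = pval, effect = beta, se = se,
       rss0 = null$rss, flagged = flagged, n = n, c = cdf)
}

null_design <- function(dataset) {
  X0 <- cbind(intercept = rep(1, dataset$n))
  if (!is.null(dataset$covariates)) X0 <- cbind(X0, dataset$covariates)
  X0
}

#' Batch-wise LMM association scan
#'
#' Estimates null-model variance components once, whitens phenotype and
#' design with the inverse Cholesky factor of `V`, and computes univariate
#' F-tests for all markers batch-wise.
#'
#' @param dataset an aligned dataset from [align_samples()].
#' @param batch_size markers per batch (result-invariant; memory/throughput
#'   knob).
#' @param vc optional precomputed `variance_components` (estimated from the
#'   dataset when `NULL`).
#' @param method variance-component criterion, `"ML"` or `"REML"`.
#' @param backend `"batch"` (whitened batched OLS, default) or `"naive"`
#'   (per-marker dense GLS reference implementation; identical results,
#'   much slower).
#' @return Object of class `permlmm_scan`: list with `table` (data.frame:
#'   `marker_id`, `chrom`, `pos`, `maf`, `effect`, `se`, `statistic`,
#'   `pvalue`), `vc`, `rss0`, `n`, `c`.
#' @export
gwas_scan <- function(dataset, batch_size = 5000L, vc = NULL,
                      method = c("ML", "REML"), backend = c("batch", "naive")) {
  stopifnot(inherits(dataset, "permlmm_dataset"))
  method <- match.arg(method)
  backend <- match.arg(backend)
  if (batch_size < 1L) usage_error("batch_size must be >= 1")
  X0 <- null_design(dataset)
  y <- as.numeric(dataset$phenotype)
  K <- dataset$kinship
  if (is.null(vc)) {
    vc <- estimate_variance_components(y, X0, K, method = method)
  }
  M <- dataset$genotype$dosages
  res <- if (backend == "batch") {
    scan_core(y, X0, M, K, vc, batch_size = batch_size)
  } else {
    scan_naive(y, X0, M, K, vc)
  }
  tab <- data.frame(
    marker_id = dataset$genotype$map$marker_id,
    chrom = dataset$genotype$map$chrom,
    pos = dataset$genotype$map$pos,
    maf = marker_maf(dataset$genotype),
    effect = res$effect,
    se = res$se,
    statistic = res$statistic,
    pvalue = res$pvalue,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  out <- list(table = tab, vc = vc, rss0 = res$rss0, n = res$n, c = res$c,
              flagged = res$flagged)
  class(out) <- "permlmm_scan"
  out
}

#' @export
print.permlmm_scan <- function(x, ...) {
  cat(sprintf(
    "permlmm scan: %d markers, n = %d, c = %d; min p = %.3g\n",
    nrow(x$table), x$n, x$c, suppressWarnings(min(x$table$pvalue, na.rm = TRUE))
  ))
  invisible(x)
}
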