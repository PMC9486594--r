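# fixtures and independent oracles shared across test files

# tiny deterministic genotype: 3 samples x 2 markers
toy_genotype <- function() {
  d <- matrix(c(0, 2, 0,
                1, 1, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("m1", "m2")))
  genotype_matrix(d, chrom = c("1", "1"), pos = c(100L, 200L))
}

# write a genotype as the package's CSV dialect and return the path
toy_genotype_csv <- function(g, path = tempfile(fileext = ".csv")) {
  write_genotype_csv(g, path)
  path
}

random_dataset <- function(n, m, seed, h2 = 0.5, rho = 0, covariates = 0) {
  g <- simulate_genotypes(n = n, m = m, rho = rho, seed = seed)
  K <- stabilize_kinship(realized_relationship(g))
  y <- draw_null_phenotype(K, sigma_g2 = h2, sigma_e2 = 1 - h2,
                           seed = seed + 1)
  covs <- NULL
  if (covariates > 0) {
    covs <- matrix(rnorm(n * covariates), n,
                   dimnames = list(rownames(g$dosages),
                                   paste0("cov", seq_len(covariates))))
  }
  align_samples(g, y, covariates = covs, kinship = K)
}

# phenotype drawn from the null LMM y ~ N(0, sigma_g2 K + sigma_e2 I)
draw_null_phenotype <- function(K, sigma_g2, sigma_e2, seed) {
  n <- nrow(K)
  V <- sigma_g2 * K + diag(sigma_e2, n)
  L <- t(chol(V))
  y <- permlmm:::with_seed(seed, as.numeric(L %*% rnorm(n)))
  setNames(y, rownames(K))
}

null_design_of <- function(ds) permlmm:::null_design(ds)

# textbook per-block OLS fit via lm(): the oracle for batch_ols
lm_block_oracle <- function(base, marker, y) {
  fit <- lm(y ~ 0 + base + marker)
  null <- lm(y ~ 0 + base)
  list(
    coef = unname(coef(fit)),
    rss = sum(resid(fit)^2),
    rss0 = sum(resid(null)^2),
    se = summary(fit)$coefficients["marker", "Std. Error"]
  )
}

# brute-force 2-D profile of the LMM likelihood on an (h2, scale-profiled)
# grid using dense Cholesky solves; independent of the eigendecomposition
# route in the package
grid_h2_oracle <- function(y, X, K, h_grid = seq(0.01, 0.99, by = 0.02)) {
  n <- length(y)
  ll <- vapply(h_grid, function(h) {
    V0 <- h * K + diag(1 - h, n)
    L <- t(chol(V0))
    yw <- forwardsolve(L, y)
    Xw <- forwardsolve(L, X)
    r <- qr.resid(qr(Xw), yw)
    s2 <- sum(r^2) / n # profiled total variance (ML)
    logdet <- 2 * sum(log(diag(L)))
    -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
  }, 0)
  h_grid[which.max(ll)]
}
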