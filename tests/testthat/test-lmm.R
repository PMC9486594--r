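test_that("with K = I only the total variance is identified and equals the OLS ML variance", {
  set.seed(21)
  n <- 60
  X <- cbind(1, rnorm(n))
  y <- as.numeric(X %*% c(1, 0.5) + rnorm(n, sd = 1.3))
  vc <- estimate_variance_components(y, X, diag(n))
  ols_ml_var <- sum(resid(lm(y ~ 0 + X))^2) / n
  expect_equal(vc$sigma_g2 + vc$sigma_e2, ols_ml_var, tolerance = 1e-6)
})

test_that("constant phenotypes are rejected", {
  expect_error(estimate_variance_components(rep(1, 10), K = diag(10)),
               "zero variance")
})

test_that("REML total variance exceeds the ML total on the K = I collapse", {
  set.seed(22)
  n <- 40
  y <- rnorm(n)
  ml <- estimate_variance_components(y, K = diag(n), method = "ML")
  reml <- estimate_variance_components(y, K = diag(n), method = "REML")
  expect_equal((reml$sigma_g2 + reml$sigma_e2) / (ml$sigma_g2 + ml$sigma_e2),
               n / (n - 1), tolerance = 1e-4)
})

test_that("whitening is exact for scaled identities and general SPD matrices", {
  x <- matrix(rnorm(20), 5)
  vc1 <- list(sigma_g2 = 0, sigma_e2 = 1)
  expect_equal(whiten(covariance_model(vc1, diag(5)), x), x)

  vc4 <- list(sigma_g2 = 0, sigma_e2 = 4)
  expect_equal(whiten(covariance_model(vc4, diag(5)), x), x / 2)

  set.seed(23)
  A <- matrix(rnorm(25), 5)
  V <- crossprod(A) + diag(5)
  cm <- covariance_model(list(sigma_g2 = 1, sigma_e2 = 0), V)
  # C^{-1} V C^{-T} = I, checked against a dense solve
  W <- whiten(cm, t(whiten(cm, V)))
  expect_equal(W, diag(5), tolerance = 1e-10)
  expect_equal(whiten(cm, x), solve(cm$C) %*% x, tolerance = 1e-10)
})

test_that("batch OLS reproduces per-block lm fits and exact fits", {
  set.seed(24)
  n <- 10
  base <- cbind(1, rnorm(n), rnorm(n)) # shared intercept + 2 covariates
  markers <- matrix(rnorm(n * 4), n)
  y <- rnorm(n)
  fit <- batch_ols(base, markers, y)
  for (j in 1:4) {
    oracle <- lm_block_oracle(base, markers[, j], y)
    expect_equal(unname(fit$coefficients[, j]), oracle$coef, tolerance = 1e-10)
    expect_equal(fit$rss[j], oracle$rss, tolerance = 1e-10)
    expect_equal(fit$rss0, oracle$rss0, tolerance = 1e-10)
    expect_equal(fit$se[j], oracle$se, tolerance = 1e-10)
  }

  # exact fit: y constructed from a known coefficient vector
  beta0 <- c(1, -2, 0.5, 3)
  y_exact <- as.numeric(cbind(base, markers[, 1]) %*% beta0)
  fit2 <- batch_ols(base, markers[, 1, drop = FALSE], y_exact)
  expect_equal(unname(fit2$coefficients[, 1]), beta0, tolerance = 1e-8)
  expect_lt(fit2$rss[1], 1e-16 * sum(y_exact^2))

  # broadcast consistency: identical blocks give identical outputs
  dup <- markers[, c(2, 2, 2)]
  fit3 <- batch_ols(base, dup, y)
  expect_equal(fit3$rss, rep(fit3$rss[1], 3))
  expect_equal(fit3$effect, rep(fit3$effect[1], 3))

  # collinear marker column is flagged, not fatal
  fit4 <- batch_ols(base, base[, 2, drop = FALSE], y)
  expect_true(fit4$flagged[1])
  expect_true(is.na(fit4$effect[1]))
})

test_that("F statistic follows the nested-model formula and clips round-off", {
  expect_equal(f_statistic(2, 2, 10, 2), 0)
  expect_equal(f_statistic(2, 1, 10, 2), 8)
  expect_equal(f_statistic(1, 1 + 1e-13, 10, 2), 0) # negative clipped
  expect_identical(f_statistic(1, 0, 10, 2), Inf)

  # with V = I it equals the textbook one-extra-regressor F test
  set.seed(25)
  n <- 30
  base <- cbind(1, rnorm(n))
  x <- rnorm(n)
  y <- rnorm(n)
  o <- lm_block_oracle(base, x, y)
  t_classic <- (n - 3) * (o$rss0 - o$rss) / o$rss
  fit <- batch_ols(base, matrix(x), y)
  expect_equal(f_statistic(fit$rss0, fit$rss, n, 3), t_classic,
               tolerance = 1e-10)
})

test_that("F p-values match quadrature and are monotone", {
  expect_equal(f_pvalue(0, 10, 2), 1)
  # numerical integration of the F(1, 8) density as an independent oracle
  dens <- function(x) df(x, 1, 8)
  p_oracle <- integrate(dens, 8, Inf, rel.tol = 1e-10)$value
  expect_equal(f_pvalue(8, 10, 2), p_oracle, tolerance = 1e-8)
  expect_equal(round(f_pvalue(8, 10, 2), 4), 0.0222, tolerance = 1e-4)

  t <- seq(0, 20, by = 0.5)
  expect_true(all(diff(f_pvalue(t, 10, 2)) < 0))
})

test_that("scan results are independent of batch size and bit-stable", {
  ds <- suppressMessages(random_dataset(n = 50, m = 80, seed = 26))
  s1 <- gwas_scan(ds, batch_size = 1)
  s2 <- gwas_scan(ds, batch_size = 80)
  s3 <- gwas_scan(ds, batch_size = 7)
  expect_equal(s1$table$statistic, s2$table$statistic, tolerance = 1e-12)
  expect_equal(s1$table$pvalue, s2$table$pvalue, tolerance = 1e-12)
  expect_equal(s3$table$statistic, s2$table$statistic, tolerance = 1e-12)

  # identical inputs give identical (bit-stable) results
  expect_identical(gwas_scan(ds)$table, gwas_scan(ds)$table)
})

test_that("test statistics are invariant to joint rescaling of the variance components", {
  ds <- suppressMessages(random_dataset(n = 40, m = 30, seed = 27))
  vc <- estimate_variance_components(ds$phenotype, null_design_of(ds), ds$kinship)
  vc_scaled <- vc
  vc_scaled$sigma_g2 <- 7 * vc$sigma_g2
  vc_scaled$sigma_e2 <- 7 * vc$sigma_e2
  s1 <- gwas_scan(ds, vc = vc)
  s2 <- gwas_scan(ds, vc = vc_scaled)
  expect_equal(s1$table$statistic, s2$table$statistic, tolerance = 1e-9)
})

test_that("adding the marker regressor never increases the residual sum of squares", {
  ds <- suppressMessages(random_dataset(n = 45, m = 60, seed = 28))
  vc <- estimate_variance_components(ds$phenotype, null_design_of(ds), ds$kinship)
  cm <- covariance_model(vc, ds$kinship)
  yw <- as.numeric(whiten(cm, ds$phenotype))
  Xw <- whiten(cm, null_design_of(ds))
  Mw <- whiten(cm, ds$genotype$dosages)
  fit <- batch_ols(Xw, Mw, yw)
  expect_true(all(fit$rss <= fit$rss0 * (1 + 1e-8)))
})

test_that("p-values are approximately uniform under the null model", {
  g <- simulate_genotypes(n = 100, m = 300, seed = 29)
  K <- stabilize_kinship(realized_relationship(g))
  y <- draw_null_phenotype(K, sigma_g2 = 0.5, sigma_e2 = 0.5, seed = 30)
  ds <- suppressMessages(align_samples(g, y, kinship = K))
  sc <- gwas_scan(ds)
  ks <- suppressWarnings(ks.test(sc$table$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})
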