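test_that("simulated genotypes are seeded hard calls at the requested frequencies", {
  g <- simulate_genotypes(n = 50, m = 30, seed = 51)
  expect_true(all(g$dosages %in% c(0, 1, 2)))
  expect_equal(dim(g$dosages), c(50L, 30L))
  g2 <- simulate_genotypes(n = 50, m = 30, seed = 51)
  expect_identical(g2$dosages, g$dosages)

  # binomial concentration: realized frequencies near the drawn ones
  n <- 2000
  m <- 40
  g3 <- simulate_genotypes(n = n, m = m, seed = 52)
  drawn <- permlmm:::with_seed(52, runif(m, 0.05, 0.5))
  realized <- colMeans(g3$dosages) / 2
  expect_true(all(abs(realized - drawn) < 0.03))
})

test_that("blockwise linkage produces correlated neighbours and independent blocks", {
  g <- simulate_genotypes(n = 400, m = 40, rho = 0.9, block_size = 20,
                          seed = 53)
  r <- cor(g$dosages)
  within <- r[1:20, 1:20][upper.tri(matrix(0, 20, 20))]
  between <- r[1:20, 21:40]
  expect_gt(mean(within), 0.4)
  expect_lt(mean(abs(between)), 0.1)
})

test_that("phenotype variance fractions are exact in-sample", {
  g <- simulate_genotypes(n = 120, m = 160, seed = 54)
  cfg <- simulation_config(n_background = 100, seed = 55)
  ph <- simulate_phenotype(g, cfg)
  expect_equal(ph$realized$background_fraction, 0.70, tolerance = 1e-6)
  expect_equal(ph$realized$causative_genetic_fraction, 0.20, tolerance = 1e-6)

  # gamma noise: fractions still exact
  cfg_g <- simulation_config(n_background = 100, noise_family = "gamma",
                             gamma_shape = 0.1, seed = 56)
  ph_g <- simulate_phenotype(g, cfg_g)
  expect_equal(ph_g$realized$background_fraction, 0.70, tolerance = 1e-6)

  # deterministic given the seed
  expect_identical(simulate_phenotype(g, cfg)$values, ph$values)

  # insufficient eligible markers
  expect_error(
    simulate_phenotype(g, simulation_config(n_background = 500, seed = 1)),
    "need"
  )
})

test_that("phenotype equals the genetic score when the noise scale is zero", {
  g <- simulate_genotypes(n = 80, m = 60, seed = 57)
  cfg <- simulation_config(n_background = 40,
                           background_variance_fraction = 1 - 1e-12,
                           seed = 58)
  ph <- simulate_phenotype(g, cfg)
  expect_lt(abs(ph$noise$scale), 1e-4)
  xc <- g$dosages[, ph$causative$marker_id]
  bg <- g$dosages[, ph$background_ids, drop = FALSE]
  # genetic part alone reproduces y up to the (negligible) noise term
  resid <- ph$values - ph$effect_size * xc
  fit <- lm(resid ~ bg)
  expect_lt(sum(residuals(fit)^2) / var(ph$values), 1e-6)
})

test_that("gamma shape controls skewness in the expected direction", {
  g <- simulate_genotypes(n = 300, m = 1100, seed = 59)
  shapes <- c("0.1", "1", "4", "normal")
  med_skew <- sapply(shapes, function(s) {
    sk <- vapply(1:50, function(r) {
      cfg <- simulation_config(
        noise_family = if (s == "normal") "normal" else "gamma",
        gamma_shape = if (s == "normal") 1 else as.numeric(s),
        seed = permlmm:::child_seed(60, match(s, shapes) * 1000 + r)
      )
      sample_skewness(simulate_phenotype(g, cfg)$values)
    }, 0)
    median(sk)
  })
  expect_gt(med_skew[["0.1"]], med_skew[["1"]])
  expect_gt(med_skew[["1"]], med_skew[["4"]])
  expect_lt(abs(med_skew[["normal"]]), 0.3)
})

test_that("hit classification applies the 50 kbp window on the right chromosome", {
  tab <- data.frame(
    marker_id = c("a", "b", "c"),
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100000L, 160000L, 100000L),
    pvalue = c(1e-8, 1, 1)
  )
  # single significant marker at the causative position
  cl <- classify_hits(tab, 1e-6, "chr1", 100000L)
  expect_true(cl$tp)
  expect_false(cl$fp)

  # significant marker 60 kb away: outside the closed +/-50 kb window
  tab2 <- tab
  tab2$pvalue <- c(1, 1e-8, 1)
  cl2 <- classify_hits(tab2, 1e-6, "chr1", 100000L)
  expect_false(cl2$tp)
  expect_true(cl2$fp)

  # exactly 50 kb away is inside (closed interval)
  tab2$pos[2] <- 150000L
  cl2b <- classify_hits(tab2, 1e-6, "chr1", 100000L)
  expect_true(cl2b$tp)

  # hits at the causative position AND on another chromosome: TP and FP
  tab3 <- tab
  tab3$pvalue <- c(1e-8, 1, 1e-8)
  cl3 <- classify_hits(tab3, 1e-6, "chr1", 100000L)
  expect_true(cl3$tp)
  expect_true(cl3$fp)

  # strict inequality: p equal to the threshold is not significant
  tab4 <- tab
  tab4$pvalue <- c(1e-6, 1, 1)
  cl4 <- classify_hits(tab4, 1e-6, "chr1", 100000L)
  expect_false(cl4$tp)

  # causative marker must be present
  expect_error(classify_hits(tab, 1e-6, "chr9", 100000L), "absent")
})

test_that("phenotype-wise FDR counts TP and FP phenotypes, allowing both at once", {
  tp <- c(rep(TRUE, 5), rep(FALSE, 5))
  fp <- c(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(phenotype_fdr(tp, fp), 0.5)

  # all phenotypes both TP and FP: double counting per definition
  expect_equal(phenotype_fdr(rep(TRUE, 50), rep(TRUE, 50)), 0.5)

  expect_equal(phenotype_fdr(rep(TRUE, 4), rep(FALSE, 4)), 0)
  expect_message(out <- phenotype_fdr(logical(3), logical(3)), "undefined")
  expect_true(is.na(out))
})

test_that("the simulation study produces a complete, reproducible table", {
  g <- simulate_genotypes(n = 40, m = 80, seed = 61)
  cfg <- simulation_config(n_background = 30)
  study <- suppressMessages(run_simulation_study(
    g, shapes = c("normal", "0.1"), replicates = 2, q = 10, seed = 62,
    config = cfg
  ))
  expect_equal(nrow(study), 4)
  expect_true(all(c("delta_star", "delta_bonf", "tp_perm", "fp_bonf") %in%
                    names(study)))
  expect_false(anyNA(study$delta_star))
  fdr <- attr(study, "fdr")
  expect_equal(nrow(fdr), 2)

  study2 <- suppressMessages(run_simulation_study(
    g, shapes = c("normal", "0.1"), replicates = 2, q = 10, seed = 62,
    config = cfg
  ))
  expect_identical(study, study2)
})

test_that("permutation thresholds recover at least as many true associations as Bonferroni for normal noise", {
  panel <- simulate_genotypes(n = 150, m = 600, maf_low = 1 / 300,
                              position_spacing = 500L, rho = 0.9, seed = 63)
  study <- suppressMessages(run_simulation_study(
    panel, shapes = "normal", replicates = 30, q = 100, seed = 64,
    config = simulation_config(n_background = 400)
  ))
  expect_gte(sum(study$tp_perm), sum(study$tp_bonf))
})
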