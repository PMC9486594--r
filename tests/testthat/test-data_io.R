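test_that("genotype CSV writes and reads back element-wise identically", {
  g <- toy_genotype()
  path <- toy_genotype_csv(g)
  g2 <- read_genotype(path, format = "csv")
  expect_identical(rownames(g2$dosages), c("A", "B", "C"))
  expect_identical(g2$map$marker_id, g$map$marker_id)
  expect_equal(g2$dosages, g$dosages)

  # a second round trip through a fresh file is still exact
  path2 <- toy_genotype_csv(g2)
  expect_equal(read_genotype(path2)$dosages, g$dosages)
})

test_that("chromosome and position are parsed from chrom_pos marker ids", {
  g <- simulate_genotypes(n = 10, m = 8, seed = 1)
  path <- toy_genotype_csv(g)
  g2 <- read_genotype(path)
  expect_identical(g2$map$chrom, g$map$chrom)
  expect_identical(g2$map$pos, g$map$pos)
})

test_that("PLINK bed/bim/fam round trip matches the CSV read", {
  g <- simulate_genotypes(n = 23, m = 17, seed = 4) # n %% 4 != 0 exercises padding
  prefix <- tempfile()
  write_plink(g, prefix)
  g2 <- read_genotype(prefix, format = "plink")
  expect_equal(g2$dosages, g$dosages)
  expect_identical(g2$map$chrom, g$map$chrom)
  expect_identical(g2$map$pos, g$map$pos)
})

test_that("PLINK dosages are flipped to count the minor allele", {
  # write a marker where A1 is the major allele (dosage mostly 2)
  d <- matrix(c(2, 2, 2, 1, 0, 0, 1, 0), nrow = 4,
              dimnames = list(paste0("s", 1:4), c("maj", "min")))
  g <- genotype_matrix(d)
  prefix <- tempfile()
  write_plink(g, prefix)
  g2 <- read_genotype(prefix, format = "plink")
  expect_equal(unname(g2$dosages[, "maj"]), c(0, 0, 0, 1)) # flipped
  expect_equal(unname(g2$dosages[, "min"]), c(0, 0, 1, 0)) # untouched
})

test_that("degenerate PLINK inputs error", {
  g <- toy_genotype()
  prefix <- tempfile()
  write_plink(g, prefix)
  # empty bim: 3 samples, 0 markers
  writeLines(character(0), paste0(prefix, ".bim"))
  expect_error(read_genotype(prefix, format = "plink"), "no markers")
  # bad magic
  write_plink(g, prefix)
  writeBin(as.raw(c(1, 2, 3, 4)), paste0(prefix, ".bed"))
  expect_error(read_genotype(prefix, format = "plink"), "magic|inconsistent")
})

test_that("phenotype reader handles missing values, replicates and bad traits", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("accession_id,FT16", "A,1.0", "B,2.0", "C,NA"), path)
  y <- read_phenotype(path, "FT16")
  expect_equal(unname(y), c(1, 2, NA))
  expect_identical(names(y), c("A", "B", "C"))

  expect_error(read_phenotype(path, "FT10"), "FT16")

  # replicates averaged with a log message
  writeLines(c("accession_id,FT16", "A,1.0", "A,3.0", "B,5.0"), path)
  expect_message(y2 <- read_phenotype(path, "FT16"), "replicate")
  expect_equal(unname(y2), c(2, 5))
  expect_identical(names(y2), c("A", "B"))
})

test_that("sample alignment intersects, drops missing and is order-invariant", {
  g <- simulate_genotypes(n = 12, m = 20, seed = 2)
  ids <- rownames(g$dosages)
  K <- stabilize_kinship(realized_relationship(g))
  y <- setNames(rnorm(12), ids)

  # phenotype lacking the first sample, plus an extra unknown sample
  y2 <- c(y[-1], unknown = 0.5)
  ds <- suppressMessages(align_samples(g, y2, kinship = K))
  expect_identical(names(ds$phenotype), ids[-1])

  # missing phenotype value drops that sample
  y3 <- y
  y3[3] <- NA
  ds3 <- suppressMessages(align_samples(g, y3, kinship = K))
  expect_false(ids[3] %in% names(ds3$phenotype))

  # kinship lacking one sample drops it everywhere
  ds4 <- suppressMessages(align_samples(g, y, kinship = K[-5, -5]))
  expect_false(ids[5] %in% names(ds4$phenotype))
  expect_identical(rownames(ds4$kinship), names(ds4$phenotype))

  # canonical order independent of phenotype ordering
  ds5 <- suppressMessages(align_samples(g, rev(y), kinship = K))
  expect_identical(names(ds5$phenotype), ids)
  expect_equal(ds5$phenotype, y[ids])
})

test_that("MAF/MAC filtering matches allele counting and is idempotent", {
  d <- cbind(
    kept = c(0, 0, 1, 2),    # freq 3/8 = 0.375
    mono = c(0, 0, 0, 0),    # monomorphic
    rare = c(0, 0, 0, 1) / 3 # MAF 1/24 ~ 0.042 (fractional dosage)
  )
  rownames(d) <- paste0("s", 1:4)
  g <- genotype_matrix(d)
  f <- suppressMessages(filter_maf(g, maf_min = 0.05))
  expect_identical(f$map$marker_id, "kept")
  expect_equal(marker_maf(f), c(kept = 0.375))

  # idempotent
  expect_equal(suppressMessages(filter_maf(f, maf_min = 0.05))$dosages, f$dosages)

  # MAC filter: minor allele count of 'kept' is 3
  expect_error(suppressMessages(filter_maf(g, maf_min = 0.05, mac_min = 4)),
               "all markers")

  expect_error(filter_maf(g, maf_min = 0.7), "maf_min")
})

test_that("results files round-trip p-values and record permutation thresholds", {
  g <- simulate_genotypes(n = 40, m = 30, seed = 9)
  ph <- simulate_phenotype(g, simulation_config(n_background = 10, seed = 9))
  fit <- suppressMessages(perm_gwas(g, ph$values, q = 12, seed = 3))
  prefix <- file.path(tempfile(), "run")
  paths <- write_results(fit, prefix)
  expect_true(all(file.exists(paths)))

  res <- read.csv(paths[["results"]])
  expect_equal(nrow(res), 30)
  expect_equal(res$pvalue, fit$scan$pvalue, tolerance = 1e-10)

  summ <- readLines(paths[["summary"]])
  expect_true(any(grepl("^maxt_threshold:", summ)))
  pmin_line <- summ[grepl("^p_min:", summ)]
  pmins <- as.numeric(strsplit(sub("^p_min: ", "", pmin_line), ",")[[1]])
  expect_equal(pmins, fit$thresholds$p_min, tolerance = 1e-12)
})
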