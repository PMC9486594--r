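# Synthetic genotypes and phenotypes.
#
# The phenotype simulator follows the study design used throughout the
# package's evaluation: a polygenic background of many small normal effects
# accounting for a fixed share of the phenotypic variance, one causative
# marker explaining a fixed share of the total genetic variance, and
# additive noise that is either normal or gamma-distributed (mean-centered)
# to manipulate skewness without moving the location.

#' Simulation configuration
#'
#' Defaults encode the reference study conditions: 1000 background markers
#' with effects drawn from N(0, 0.1^2), a polygenic background accounting
#' for 70% of the phenotypic variance, a causative marker explaining 20% of
#' the total genetic variance, markers sampled at minor allele frequency
#' >= 5%.
#'
#' @param n_background number of polygenic background markers.
#' @param background_effect_sd SD of per-marker background effects.
#' @param background_variance_fraction share of phenotypic variance from the
#'   background (in-sample, exact by construction).
#' @param causative_variance_fraction share of the total genetic variance
#'   from the causative marker.
#' @param noise_family `"normal"` or `"gamma"`.
#' @param gamma_shape shape parameter of the gamma noise (used when
#'   `noise_family = "gamma"`; smaller = more skewed).
#' @param maf_min minimum minor allele frequency for sampled markers.
#' @param seed RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_background = 1000L,
                              background_effect_sd = 0.1,
                              background_variance_fraction = 0.70,
                              causative_variance_fraction = 0.20,
                              noise_family = c("normal", "gamma"),
                              gamma_shape = 1,
                              maf_min = 0.05,
                              seed = 1L) {
  noise_family <- match.arg(noise_family)
  if (n_background < 1L) usage_error("n_background must be >= 1")
  stopifnot(background_variance_fraction > 0, background_variance_fraction < 1,
            causative_variance_fraction > 0, causative_variance_fraction < 1)
  if (noise_family == "gamma" && gamma_shape <= 0) {
    usage_error("gamma_shape must be positive")
  }
  structure(
    list(
      n_background = as.integer(n_background),
      background_effect_sd = background_effect_sd,
      background_variance_fraction = background_variance_fraction,
      causative_variance_fraction = causative_variance_fraction,
      noise_family = noise_family,
      gamma_shape = gamma_shape,
      maf_min = maf_min,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Simulate a synthetic genotype panel
#'
#' Per marker, an allele frequency is drawn uniformly in
#' `[maf_low, maf_high]` and dosages are binomial(2, p) per sample.
#' Optionally, adjacent markers within blocks share a latent per-haplotype
#' Gaussian signal (correlation `rho`), creating blockwise linkage
#' disequilibrium so that physical windows around a causative marker are
#' non-trivial. Positions are laid out at fixed spacing per chromosome.
#'
#' @param n samples.
#' @param m markers.
#' @param maf_low,maf_high allele-frequency range (`0 < maf_low <= maf_high
#'   <= 0.5`).
#' @param markers_per_chromosome markers per chromosome (default: spread
#'   over 5 chromosomes).
#' @param position_spacing base pairs between adjacent markers.
#' @param rho latent haplotype correlation within blocks (0 = independent
#'   markers).
#' @param block_size markers per linkage block (used when `rho > 0`).
#' @param seed RNG seed.
#' @return A [genotype_matrix()] with hard-call dosages in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(n, m, maf_low = 0.05, maf_high = 0.5,
                               markers_per_chromosome = ceiling(m / 5),
                               position_spacing = 1000L,
                               rho = 0, block_size = 20L, seed = 1L) {
  if (maf_low <= 0 || maf_low > maf_high || maf_high > 0.5) {
    usage_error("need 0 < maf_low <= maf_high <= 0.5")
  }
  if (rho < 0 || rho >= 1) usage_error("rho must lie in [0, 1)")
  with_seed(seed, {
    p <- runif(m, maf_low, maf_high)
    if (rho == 0) {
      d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
    } else {
      # Gaussian-copula haplotypes: within a block, both haplotypes of a
      # sample share a latent normal; marker allele = indicator that a
      # correlated normal falls below qnorm(p_j).
      block <- (seq_len(m) - 1L) %/% block_size + 1L
      nb <- max(block)
      d <- matrix(0L, n, m)
      for (hap in 1:2) {
        zb <- matrix(rnorm(n * nb), n, nb) # block-level latent per haplotype
        eps <- matrix(rnorm(n * m), n, m)
        z <- rho * zb[, block, drop = FALSE] + sqrt(1 - rho^2) * eps
        d <- d + (z < matrix(qnorm(p), n, m, byrow = TRUE))
      }
    }
    storage.mode(d) <- "double"
    rownames(d) <- sprintf("acc_%04d", seq_len(n))
    chrom_idx <- (seq_len(m) - 1L) %/% markers_per_chromosome + 1L
    offset <- (seq_len(m) - 1L) %% markers_per_chromosome
    pos <- as.integer(position_spacing * (offset + 1L))
    chrom <- sprintf("chr%d", chrom_idx)
    colnames(d) <- sprintf("%s_%d", chrom, pos)
    genotype_matrix(d, chrom = chrom, pos = pos)
  })
}

#' Simulate a phenotype with polygenic background and one causative marker
#'
#' Algorithm: (1) sample `n_background + 1` markers with minor allele
#' frequency at least `maf_min`; one is designated causative; (2) build the
#' background score `g = sum_i x_i beta_i` with
#' `beta_i ~ N(0, background_effect_sd^2)`; (3) draw noise from the
#' configured family (gamma draws are centered by their mean) and rescale
#' it so that the in-sample ratio `Var(g) / Var(g + e)` equals
#' `background_variance_fraction` exactly; (4) add a causative effect
#' `a * x_c` with `a` chosen so that `Var(a x_c)` equals
#' `causative_variance_fraction / (1 - causative_variance_fraction) *
#' Var(g)` in-sample; (5) `y = g + a x_c + e`.
#'
#' @param genotype a `permlmm_genotype` with at least `n_background + 1`
#'   eligible markers.
#' @param config a [simulation_config()].
#' @return Object of class `simulated_phenotype`: list with `values` (named
#'   vector), `causative` (marker_id/chrom/pos), `background_ids`,
#'   `realized` (variance fractions), `noise` (family, shape, scale),
#'   `config`.
#' @export
simulate_phenotype <- function(genotype, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  maf <- marker_maf(genotype)
  eligible <- which(maf >= config$maf_min)
  need <- config$n_background + 1L
  if (length(eligible) < need) {
    data_error(sprintf(
      "only %d markers at MAF >= %g; need %d",
      length(eligible), config$maf_min, need
    ))
  }
  n <- nrow(genotype$dosages)
  with_seed(config$seed, {
    picked <- sample(eligible, need)
    causative_idx <- picked[1L]
    background_idx <- sort(picked[-1L])
    beta <- rnorm(config$n_background, 0, config$background_effect_sd)
    g <- as.numeric(genotype$dosages[, background_idx, drop = FALSE] %*% beta)
    vg <- var(g)
    if (vg == 0) numeric_error("degenerate background score (zero variance)")
    # noise via quantile transform of one uniform draw: with a shared seed,
    # noise sets of different families/shapes are comonotone (common random
    # numbers), so between-set comparisons are paired on everything except
    # the noise distribution itself
    u <- runif(n)
    e_raw <- switch(config$noise_family,
      normal = qnorm(u),
      gamma = qgamma(u, shape = config$gamma_shape, rate = 1) - config$gamma_shape
    )
    # scale noise so Var(g) / Var(g + s e) = f exactly in-sample
    f <- config$background_variance_fraction
    target <- vg / f              # required Var(g + s e)
    ve <- var(e_raw)
    cge <- cov(g, e_raw)
    disc <- cge^2 + ve * (target - vg)
    if (ve == 0 || disc < 0) numeric_error("cannot scale noise to the requested variance fraction")
    s <- (-cge + sqrt(disc)) / ve
    e <- s * e_raw
    # causative effect: Var(a x_c) = cf/(1-cf) * Var(g)
    cf <- config$causative_variance_fraction
    xc <- genotype$dosages[, causative_idx]
    vx <- var(xc)
    if (vx == 0) numeric_error("causative marker is monomorphic in-sample")
    a <- sqrt(cf / (1 - cf) * vg / vx)
    y <- g + a * xc + e
    realized <- list(
      background_fraction = vg / var(g + e),
      causative_genetic_fraction = var(a * xc) / (vg + var(a * xc))
    )
    out <- list(
      values = setNames(y, rownames(genotype$dosages)),
      causative = genotype$map[causative_idx, , drop = FALSE],
      background_ids = genotype$map$marker_id[background_idx],
      effect_size = a,
      realized = realized,
      noise = list(family = config$noise_family,
                   shape = if (config$noise_family == "gamma") config$gamma_shape else NA_real_,
                   scale = s),
      config = config
    )
    class(out) <- "simulated_phenotype"
    out
  })
}

#' @export
print.simulated_phenotype <- function(x, ...) {
  cat(sprintf(
    "simulated phenotype: n = %d, causative %s (%s:%d), noise = %s%s, background fraction = %.4f\n",
    length(x$values), x$causative$marker_id, x$causative$chrom,
    x$causative$pos, x$noise$family,
    if (x$noise$family == "gamma") sprintf("(shape %.3g)", x$noise$shape) else "",
    x$realized$background_fraction
  ))
  invisible(x)
}

#' Classify a scan as true/false positive around a causative marker
#'
#' A phenotype is a true positive (TP) if any marker with `p < threshold`
#' (strict) lies within the closed window `causative_pos +/- window` on the
#' causative chromosome, and a false positive (FP) if any significant
#' marker lies outside that window or on another chromosome. A phenotype
#' can be both at once.
#'
#' @param scan a `permlmm_scan`, [perm_gwas()] fit, or the scan table
#'   data.frame.
#' @param threshold significance threshold in `(0, 1)`.
#' @param causative_chrom,causative_pos location of the causative marker
#'   (must be present among the scanned markers).
#' @param window half-width in base pairs (default 50000).
#' @return List with logical `tp`, `fp`, and the significant marker count.
#' @export
classify_hits <- function(scan, threshold, causative_chrom, causative_pos,
                          window = 50000L) {
  tab <- if (inherits(scan, "perm_gwas")) scan$scan
  else if (inherits(scan, "permlmm_scan")) scan$table
  else scan
  if (threshold <= 0 || threshold >= 1) usage_error("threshold must lie in (0, 1)")
  present <- tab$chrom == causative_chrom & tab$pos == causative_pos
  if (!any(present)) data_error("causative marker absent from scan results")
  sig <- !is.na(tab$pvalue) & tab$pvalue < threshold
  in_window <- tab$chrom == causative_chrom &
    abs(tab$pos - causative_pos) <= window
  list(
    tp = any(sig & in_window),
    fp = any(sig & !in_window),
    n_significant = sum(sig)
  )
}

#' Phenotype-wise false discovery rate
#'
#' `FDR = FP / (TP + FP)` over a set of simulated phenotypes, where TP and
#' FP count phenotypes flagged true/false positive (a phenotype can count
#' in both). Returns `NA` with a log message when no phenotype is TP or FP.
#'
#' @param tp,fp logical vectors over phenotypes (same length).
#' @return The FDR in `[0, 1]`, or `NA`.
#' @export
phenotype_fdr <- function(tp, fp) {
  stopifnot(length(tp) == length(fp))
  ntp <- sum(tp, na.rm = TRUE)
  nfp <- sum(fp, na.rm = TRUE)
  if (ntp + nfp == 0L) {
    log_msg("no TP or FP phenotypes; FDR undefined")
    return(NA_real_)
  }
  nfp / (ntp + nfp)
}

#' Run a simulation study over noise shapes
#'
#' Simulates `replicates` phenotypes per noise set on one genotype panel,
#' runs the permutation-based scan on each (kinship and its
#' eigendecomposition computed once from the panel), and records per
#' phenotype the maxT and Bonferroni thresholds and TP/FP flags under each,
#' plus set-level phenotype-wise FDRs.
#'
#' @param genotype a `permlmm_genotype` panel (all markers are scanned).
#' @param shapes character vector of noise sets: `"normal"` or a gamma
#'   shape value as a string (e.g. `"0.1"`).
#' @param replicates phenotypes per set.
#' @param q permutations per phenotype.
#' @param alpha target FWER.
#' @param seed base seed; per-phenotype seeds are derived from it.
#' @param config base [simulation_config()] (noise family/shape and seed are
#'   overridden per set/replicate).
#' @param batch_size markers per scan batch.
#' @param path optional output prefix; writes `<path>_study.csv` and
#'   `<path>_fdr.csv`.
#' @return data.frame with one row per phenotype (`set`, `replicate`,
#'   `sim_seed`, `skewness`, `delta_star`, `delta_bonf`, TP/FP flags per
#'   threshold, `m_tested`); the per-set FDR table is in attribute `"fdr"`.
#' @export
run_simulation_study <- function(genotype,
                                 shapes = c("normal", "0.1", "1", "2", "3", "4"),
                                 replicates = 50L, q = 100L, alpha = 0.05,
                                 seed = 1L, config = simulation_config(),
                                 batch_size = 5000L, path = NULL) {
  K <- stabilize_kinship(realized_relationship(genotype))
  ids <- sample_ids(genotype)
  m <- ncol(genotype$dosages)
  rows <- vector("list", length(shapes) * replicates)
  i <- 0L
  for (si in seq_along(shapes)) {
    shape <- shapes[si]
    for (r in seq_len(replicates)) {
      i <- i + 1L
      # seed depends on the replicate only: noise sets share marker
      # sampling, background effects, noise uniforms and permutations
      sim_seed <- child_seed(seed, r)
      cfg <- config
      if (shape == "normal") {
        cfg$noise_family <- "normal"
      } else {
        cfg$noise_family <- "gamma"
        cfg$gamma_shape <- as.numeric(shape)
      }
      cfg$seed <- sim_seed
      ph <- simulate_phenotype(genotype, cfg)
      ds <- align_samples(genotype, ph$values, kinship = K)
      fit <- perm_gwas(ds, q = q, alpha = alpha,
                       seed = child_seed(sim_seed, 1),
                       batch_size = batch_size)
      th <- fit$thresholds
      cl_perm <- classify_hits(fit, th$maxt, ph$causative$chrom, ph$causative$pos)
      cl_bonf <- classify_hits(fit, th$bonferroni, ph$causative$chrom, ph$causative$pos)
      rows[[i]] <- data.frame(
        set = shape,
        replicate = r,
        sim_seed = sim_seed,
        skewness = sample_skewness(ph$values),
        delta_star = th$maxt,
        delta_bonf = th$bonferroni,
        tp_perm = cl_perm$tp, fp_perm = cl_perm$fp,
        tp_bonf = cl_bonf$tp, fp_bonf = cl_bonf$fp,
        m_tested = th$m,
        stringsAsFactors = FALSE
      )
    }
  }
  study <- do.call(rbind, rows)
  fdr <- do.call(rbind, lapply(split(study, study$set), function(s) {
    data.frame(
      set = s$set[1L],
      fdr_perm = phenotype_fdr(s$tp_perm, s$fp_perm),
      fdr_bonf = phenotype_fdr(s$tp_bonf, s$fp_bonf),
      tp_perm = sum(s$tp_perm), fp_perm = sum(s$fp_perm),
      tp_bonf = sum(s$tp_bonf), fp_bonf = sum(s$fp_bonf),
      median_delta_star = median(s$delta_star),
      stringsAsFactors = FALSE
    )
  }))
  rownames(fdr) <- NULL
  attr(study, "fdr") <- fdr
  if (!is.null(path)) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    write.csv(study, paste0(path, "_study.csv"), row.names = FALSE)
    write.csv(fdr, paste0(path, "_fdr.csv"), row.names = FALSE)
  }
  study
}
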