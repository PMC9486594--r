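---
title: "Permutation-based significance thresholds for mixed-model GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-based significance thresholds for mixed-model GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permlmm)
```

## The model and its assumptions

For each of `m` markers, `permlmm` fits the linear mixed model

$$ y = X_j\beta + u + \epsilon, \qquad u \sim N(0,\sigma_g^2 K), \quad
   \epsilon \sim N(0,\sigma_e^2 I), $$

where `y` is the phenotype of `n` samples, `X_j` collects an intercept,
optional covariates, and the dosage of marker `j` (`c` fixed effects in
total), and `K` is a genetic similarity matrix. The random effect `u`
absorbs the polygenic background and with it population structure and
cryptic relatedness; what remains testable per marker is its fixed effect.
The model assumes an additive dosage effect, Gaussian residuals, and that
`K` captures the confounding genetic covariance. Variance components are
estimated **once on the null model** (no marker) and reused for every
marker's alternative model; this is the standard approximation that makes
genome-wide scans affordable, and it is exact under the null.

Marker `j` is tested with the F statistic
$t_j = (n-c)\,(\mathrm{RSS}_0 - \mathrm{RSS}_j)/\mathrm{RSS}_j$ against
$F(1, n-c)$.

## Variance components

Writing $\delta = \sigma_e^2/\sigma_g^2$ and $K = U S U^\top$, the
likelihood profiles analytically over $\beta$ and the overall scale,
leaving a one-dimensional criterion in $\delta$. `permlmm` evaluates that
profile on a 101-point logarithmic grid over $[10^{-5}, 10^5]$ and then
refines the best bracket with Brent search (`stats::optimize`,
tolerance $10^{-6}$ in $\log\delta$). The eigendecomposition is computed
once and reused across permutations, which re-estimate $\delta$ on the
permuted phenotype. Maximum likelihood is the default criterion because
the scan's test is a fixed-effects F test with variance components
treated as known; REML is available (`method = "REML"`) for users who
prefer unbiased variance components — thresholds change very little
either way because the F statistic is invariant to a joint rescaling of
$(\sigma_g^2, \sigma_e^2)$.

## Whitening and batched regression

With $V = \sigma_g^2 K + \sigma_e^2 I = CC^\top$ (lower-triangular
Cholesky), pre-multiplying `y` and each design block by $C^{-1}$ turns the
generalized least-squares problem into ordinary least squares. `permlmm`
never forms $C^{-1}$: whitening is done by triangular forward
substitution, and all markers of a scan are whitened in a single
triangular solve. Every per-marker design shares the whitened base
(intercept + covariates), so the batched regression residualizes the
phenotype and all marker columns against the base once and reduces each
marker test to univariate cross-products of residuals. Two numerical
choices matter here:

* residual cross-products rather than raw normal equations — the raw form
  subtracts two large, nearly equal quantities when $V$ is close to
  singular (heritability near 1) and loses up to five digits;
* negative statistics from round-off are clipped to 0 (`p = 1`), and a
  marker whose whitened column is numerically collinear with the base
  (residual sum of squares below $10^{-10}$ of its raw sum of squares,
  e.g. monomorphic markers) is flagged `NA` rather than fatal; flagged
  markers are excluded from permutation maxima and from the tested-marker
  count `m` used by both thresholds.

The `batch_size` argument only controls memory/throughput; results are
independent of it (tested to $10^{-12}$). A `backend = "naive"` reference
implementation (per-marker dense GLS solves) is retained for
cross-checking. For PLINK data with a precomputed kinship,
`perm_gwas_chunked()` streams markers from the SNP-major `.bed` file in
chunks so the full dosage matrix never has to be resident.

## The maxT threshold

The phenotype is permuted `q` times against fixed genotype, covariates
and `K`. Permutation destroys genotype–phenotype association but keeps
the phenotype's marginal distribution, so model violations (skewness) are
present under the empirical null too. For each permutation the scan is
repeated — including variance-component re-estimation, since the permuted
trait has its own (usually near-zero) heritability — and the minimal
p-value $p_{\min}^{(k)}$ is recorded. The threshold is the
$\alpha$-quantile of the $p_{\min}^{(k)}$, realized as the
$\max(1, \lfloor\alpha q\rfloor)$-th order statistic; significance is
declared by $p < \delta^*$ (strict). This convention guarantees estimated
FWER $\le \alpha$ whenever $\alpha q \ge 1$ and degrades conservatively
(smallest $p_{\min}$) for tiny `q`. Different percentile conventions move
$\delta^*$ by one order statistic; at the default `q = 100`,
$\alpha = 0.05$ this is the difference between the 5th and 6th smallest
value and is well inside the Monte Carlo noise of the threshold itself.

Covariates are intentionally **not** permuted: the empirical null keeps
the covariate structure of the observed analysis and only breaks the
genotype–phenotype link. Per-marker Westfall–Young adjusted p-values
(share of permutations whose genome-wide maximum beats the marker) and
pooled permutation p-values (share of the whole $q \times m$ permuted
statistic pool at or above the marker; optional add-one smoothing keeps
them away from exact zero) are reported alongside.

`q = 0` degrades `perm_gwas()` to a plain batched LMM scan with only the
Bonferroni threshold.

## What the synthetic data emulate

`simulate_genotypes()` draws per-marker allele frequencies uniformly on
`[maf_low, maf_high]` and dosages binomially; with `rho > 0`, markers
within blocks share a latent per-haplotype Gaussian (a Gaussian copula),
creating blockwise linkage disequilibrium. `simulate_phenotype()` builds a
polygenic background from 1000 markers with $N(0, 0.1^2)$ effects,
rescales noise so the background explains exactly 70% of the in-sample
phenotypic variance, and adds one causative marker explaining 20% of the
total genetic variance ($\mathrm{Var}(a x_c) = \tfrac{0.2}{0.8}
\mathrm{Var}(g)$); background and causative markers are sampled at
MAF ≥ 5%. Noise is either normal or mean-centered gamma with shape in
$\{0.1, 1, 2, 3, 4\}$ — smaller shape, heavier right skew. Scaling is
empirical (in-sample ratios exact, checked to $10^{-6}$), noise is scaled
before the causative term is added, and realized fractions are reported.
Noise draws are quantile transforms of one uniform vector, so runs that
share a seed but differ in the noise family are paired on everything
except the noise distribution (common random numbers) — between-set
comparisons of thresholds and FDR are then far less noisy than
independent draws would allow.

The evaluation panel is a deliberate, 1000-fold scaled-down stand-in for
a fully imputed association panel: `n = 200` samples, `m = 2400` markers
on 5 chromosomes at 500 bp spacing, LD blocks of 20 markers with
`rho = 0.9`, and allele frequencies down to the segregating minimum
`1/(2n)`. Three features are essential and intentional:

* **LD** makes the effective number of tests smaller than `m`, which is
  why the maxT threshold is *less* stringent than Bonferroni for normal
  phenotypes;
* **rare alleles** are what skewed phenotypes latch onto: a handful of
  carriers coinciding with phenotypic outliers produces extreme
  statistics, under permutation as in the observed scan, which is why the
  maxT threshold *tightens* as noise shape decreases and why a fixed
  Bonferroni cut-off accumulates false-positive phenotypes there;
* positions at fixed spacing make the ±50 kbp true-positive window around
  the causative marker meaningful (an LD block spans 10 kbp, well inside
  the window).

What the synthetic panel does **not** model: realistic site-frequency
spectra (frequencies are uniform by construction), long-range LD and
population admixture, genotyping error or missingness patterns, and the
sheer marker density of imputed data. Passing the study here shows the
machinery produces the right qualitative behaviour (threshold direction,
FWER control, FDR ordering) at desk scale; absolute FDR values on real
data depend on the real frequency spectrum and LD and will differ.

## Study design and problem sizes

The packaged evaluation (tests and `scripts/acceptance.R`) uses sizes
chosen to make each check sharp but cheap on one CPU: oracle equivalence
at `n = 100, m = 500`; the permutation engine against a loop of plain
scans at `q = 3, n = 50, m = 20`; FWER calibration with 200 independent
null replicates at `n = 100, m = 300, q = 100` (the exact binomial 99%
band around $\alpha = 0.05$ at 200 replicates is about `[0.01, 0.12]`);
heritability recovery at `n = 600` with `K` from 2000 markers; and the
noise-shape study with 20 phenotypes per set at `q = 100`. Empirically
100 permutations give a stable threshold estimate. The strong study-level
conclusions — the sharp tightening of the maxT threshold for shape 0.1,
the FDR ordering for that set, and the normal-noise threshold sitting
above Bonferroni — reproduce across seeds. The small separation between
the mildly skewed shapes 4 and 2 (phenotype skewness ≈ 0.1 vs ≈ 0.23
after the variance split) is at the edge of what 20 replicates on a
2400-marker panel can resolve, even with the common-random-number
pairing, and its ordering can flip between seeds; at the reference scale
(3M markers, 50 phenotypes per set) the gradient is clearer.

## Conventions and edge cases

* Dosages count the **minor** allele; PLINK input is flipped per marker
  where needed (CSV input is taken as-is so CSV round trips are exact).
  Missing calls are mean-imputed per marker at load time.
* Positions are 1-based; the true/false-positive window is a closed
  interval; markers are sorted by (chromosome, position) on load.
* Replicate phenotype rows for one sample are averaged, with a log
  message.
* Kinship defaults to the VanRaden realized relationship
  $K = WW^\top / (2\sum_j p_j(1-p_j))$ with columns centered by $2p_j$,
  computed from the analysis samples after alignment; any user matrix can
  be supplied instead. Since only `K`'s shape matters to the F statistics
  (joint rescaling of the variance components cancels), the choice of
  scaling convention does not move p-values. A positive semi-definite `K`
  is ridged with the smallest of $\{10^{-10}, 10^{-8}, 10^{-6},
  10^{-4}\}$ that makes its Cholesky succeed.
* Permutations whose variance-component optimization fails are dropped
  from the maxima with a warning; the permutation stream is materialized
  up front from the seed, so results do not depend on batch sizes.

## Known limitations

Binary traits need a generalized LMM and are out of scope, as are
multi-random-effect models, per-marker variance-component re-estimation,
residual-permutation schemes (Freedman–Lane), VCF/BGEN input, and HDF5
containers (chunked scanning is provided through PLINK files instead).
The permutation engine recomputes `O(q)` full scans; for very large
panels use the chunked PLINK path and a precomputed kinship.

```{r example}
g <- simulate_genotypes(n = 80, m = 400, maf_low = 1 / 160, rho = 0.9,
                        position_spacing = 500, seed = 2)
ph <- simulate_phenotype(g, simulation_config(n_background = 200, seed = 2))
fit <- perm_gwas(g, ph$values, q = 50, seed = 2)
fit
```
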