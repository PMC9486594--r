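# permlmm

Linear mixed model (LMM) genome-wide association scans with
permutation-based significance thresholds.

## The problem

GWAS tests every genetic marker for association with a quantitative trait.
With `m` tests the significance threshold must control the family-wise
error rate (FWER); the standard Bonferroni cut-off `α/m` assumes
independent tests and normally distributed residuals. Real genotype
matrices are full of correlated (linked) markers, and real phenotypes are
often skewed — so Bonferroni is too conservative for normal traits (lost
power) and not conservative enough for skewed ones (spurious hits,
typically rare alleles lining up with phenotypic outliers).

`permlmm` implements the Westfall–Young *maxT* permutation alternative on
top of an LMM, for users running plant/animal/human association scans on
quantitative traits who want an FWER threshold that adapts to their
phenotype instead of only to the number of tests.

## The model

Per marker `j`, the mixed model is

    y = X_j β + u + ε,   u ~ N(0, σ²_g K),   ε ~ N(0, σ²_e I)

with `K` the kinship (realized relationship) matrix correcting for
population structure. Variance components are estimated once on the null
model by maximum (or restricted maximum) likelihood, profiled over
`δ = σ²_e/σ²_g` after one eigendecomposition of `K`. With
`V = σ²_g K + σ²_e I = C Cᵀ`, whitening by `C⁻¹` (triangular solves) turns
generalized least squares into ordinary least squares, and all markers are
tested batch-wise through shared residualized cross-products. Each marker
gets the F statistic

    t_j = (n − c) (RSS₀ − RSS_j) / RSS_j,   p_j = P(F(1, n−c) ≥ t_j).

For the permutation threshold the phenotype is permuted `q` times
(genotype, covariates and `K` fixed); for every permutation the variance
components are re-estimated, all markers re-tested, and the minimal
p-value `p_min^(k)` recorded. The *maxT* threshold is the α-quantile of
the `p_min^(k)` (the `max(1, ⌊αq⌋)`-th smallest), which controls
FWER ≤ α while adapting to marker correlation and phenotype shape.
Westfall–Young adjusted per-marker p-values and pooled
permutation-adjusted p-values are also provided.

## Worked example

```r
library(permlmm)

# synthetic panel: 200 samples, 2400 markers in LD blocks, plus a
# phenotype with a polygenic background (70% of variance) and one
# causative marker (20% of the genetic variance)
g   <- simulate_genotypes(n = 200, m = 2400, maf_low = 1/400,
                          position_spacing = 500, rho = 0.9, seed = 101)
ph  <- simulate_phenotype(g, simulation_config(seed = 7))
fit <- perm_gwas(g, ph$values, q = 100, seed = 7)
print(fit)
#> Permutation-based LMM GWAS
#>   samples: 200, markers tested: 2394, fixed effects: 2
#>   sigma_g2 = 7.386, sigma_e2 = 7.386e-05 (h2 = 1.000)
#>   Bonferroni threshold (alpha = 0.05): 2.09e-05
#>   maxT permutation threshold (q = 100): 2.49e-05

head(summary(fit)$top, 3)
#>        marker_id chrom    pos  maf    effect        se statistic       pvalue p_adj_maxt
#> 1656 chr4_108000  chr4 108000 0.10  2.220347 0.3920988  32.06644 5.185943e-08       0.00
#> 1391 chr3_215500  chr3 215500 0.05 -1.933436 0.5085053  14.45669 1.909310e-04       0.26
#> 1565  chr4_62500  chr4  62500 0.05  1.795210 0.5252530  11.68136 7.662411e-04       0.78

ph$causative$marker_id
#> [1] "chr4_108000"
```

The top hit is the simulated causative marker (`chr4_108000`), the only
marker below either threshold; its Westfall–Young adjusted p-value is 0
(no permutation produced a larger genome-wide maximum). The phenotype is
normally distributed here, so the maxT threshold (2.49e-05) is *less*
stringent than Bonferroni (2.09e-05) — the permutations see that the 2394
tests are not independent. For skewed phenotypes the same machinery
tightens the threshold instead; `run_simulation_study()` quantifies both
effects and the phenotype-wise false discovery rate of each threshold.

`plot(fit)` draws a Manhattan plot with both thresholds. Pipelines can be
driven from files (`CSV` or PLINK `bed/bim/fam` genotypes, CSV phenotypes,
covariates, precomputed kinship) via `run_gwas()`/`gwas_config()` or the
shell wrapper:

```sh
Rscript inst/cli/permlmm.R --genotype geno.csv --phenotype pheno.csv \
  --trait FT10 --maf 0.05 --perm 100 --seed 42 --out results/
```

Large PLINK files can be scanned in marker chunks without loading the full
matrix (`--chunk`, requires `--kinship`).

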