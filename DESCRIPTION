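Package: permlmm
Title: Permutation-Based Linear Mixed Model Genome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Linear mixed model (LMM) genome-wide association scans with
    batch-wise generalized least squares via Cholesky whitening, and
    permutation-based significance thresholds after the Westfall-Young maxT
    procedure, controlling the family-wise error rate for both normal and
    skewed phenotypes. Includes a realized-relationship kinship estimator,
    PLINK and CSV genotype input with minor-allele-frequency filtering,
    a phenotype simulator with a polygenic background and gamma-distributed
    noise, and phenotype-wise false-discovery-rate evaluation of Bonferroni
    versus permutation thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
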