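#' Realized relationship (VanRaden) kinship matrix
#'
#' Estimates genetic similarity from genome-wide markers as
#' \deqn{K = W W^T / (2 \sum_j p_j (1 - p_j)),}
#' where `W` is the dosage matrix with each marker column centered by twice
#' its allele frequency `p_j`. Allele frequencies are computed from the
#' supplied (analysis) samples. On this scale the mean diagonal is close to
#' 1 for an outbred panel, which keeps variance components on a
#' heritability-friendly scale. Monomorphic markers contribute nothing to
#' either numerator or denominator.
#'
#' @param genotype a `permlmm_genotype` without missing dosages.
#' @return Symmetric `n x n` numeric matrix with sample dimnames.
#' @export
realized_relationship <- function(genotype) {
  d <- genotype$dosages
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) data_error("all markers monomorphic; kinship undefined")
  w <- sweep(d, 2L, 2 * p, `-`)
  k <- tcrossprod(w) / denom
  k <- (k + t(k)) / 2
  dimnames(k) <- list(rownames(d), rownames(d))
  k
}

#' Stabilize a kinship matrix for Cholesky factorization
#'
#' The covariance `V = sigma_g2 * K + sigma_e2 * I` must admit a Cholesky
#' factor. If `chol(K)` fails (K only positive semi-definite), the smallest
#' ridge from `1e-10, 1e-8, 1e-6, 1e-4` whose addition to the diagonal makes
#' the factorization succeed is applied, with a log message. Positive
#' definite input is returned unchanged.
#'
#' @param K symmetric numeric matrix.
#' @param tol symmetry tolerance.
#' @return Stabilized matrix (attribute `"ridge"` records the ridge used).
#' @export
stabilize_kinship <- function(K, tol = 1e-8) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) data_error("kinship must be square")
  asym <- max(abs(K - t(K)))
  if (asym > tol) data_error(sprintf("kinship asymmetric beyond tolerance (%.3g)", asym))
  K <- (K + t(K)) / 2
  for (ridge in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    Kr <- K + diag(ridge, nrow(K))
    ok <- !inherits(try(chol(Kr), silent = TRUE), "try-error")
    if (ok) {
      if (ridge > 0) {
        log_msg("added ridge %g to kinship diagonal for Cholesky stability", ridge)
        attr(Kr, "ridge") <- ridge
      }
      return(Kr)
    }
  }
  numeric_error("kinship not positive semi-definite; no ridge in the ladder succeeded")
}

#' Read a kinship matrix from CSV
#'
#' Expects a square matrix with sample identifiers as header row and first
#' column. Mild asymmetry (within `tol`) is symmetrized by averaging with
#' the transpose; larger asymmetry is an error.
#'
#' @param path CSV path.
#' @param tol asymmetry tolerance.
#' @return Symmetric numeric matrix with sample dimnames.
#' @export
read_kinship <- function(path, tol = 1e-8) {
  if (!file.exists(path)) data_error(sprintf("kinship file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 row.names = 1L)
  K <- as.matrix(df)
  if (nrow(K) != ncol(K)) {
    data_error(sprintf("kinship matrix is %d x %d, not square", nrow(K), ncol(K)))
  }
  if (!is.numeric(K)) data_error("non-numeric kinship entries")
  if (is.null(rownames(K)) || is.null(colnames(K))) {
    data_error("kinship CSV must carry sample identifiers")
  }
  if (!setequal(rownames(K), colnames(K))) {
    data_error("kinship row and column identifiers differ")
  }
  K <- K[, rownames(K), drop = FALSE]
  asym <- max(abs(K - t(K)))
  if (asym > tol) {
    data_error(sprintf("kinship asymmetric beyond tolerance (%.3g)", asym))
  }
  if (asym > 0) K <- (K + t(K)) / 2
  K
}

#' Write a kinship matrix to CSV
#'
#' Inverse of [read_kinship()].
#'
#' @param K matrix with sample dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(K, path) {
  write.csv(as.data.frame(K), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
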