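#' Construct a genotype matrix
#'
#' Container for allele dosages of `n` samples at `m` markers, together with
#' marker metadata (chromosome, 1-based base-pair position). Dosages count
#' copies of one allele and lie in `[0, 2]`; fractional values are allowed
#' for imputed data. Markers are sorted by (chromosome, position) on
#' construction.
#'
#' @param dosages numeric `n x m` matrix; rownames are sample identifiers,
#'   colnames marker identifiers (generated if absent).
#' @param chrom character vector of chromosome labels, length `m`
#'   (default `"1"` for all markers).
#' @param pos integer vector of 1-based positions, length `m`
#'   (default `1:m`).
#' @return An object of class `permlmm_genotype`: a list with elements
#'   `dosages` (matrix) and `map` (data.frame with `marker_id`, `chrom`,
#'   `pos`).
#' @export
genotype_matrix <- function(dosages, chrom = NULL, pos = NULL) {
  if (!is.matrix(dosages) || !is.numeric(dosages)) {
    data_error("dosages must be a numeric matrix (samples x markers)")
  }
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (n < 2L) data_error("need at least 2 samples")
  if (m < 1L) data_error("need at least 1 marker")
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("sample_", seq_len(n))
  }
  if (anyDuplicated(rownames(dosages))) {
    data_error("duplicate sample identifiers in genotype")
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("marker_", seq_len(m))
  }
  if (anyNA(dosages)) {
    data_error("dosages contain missing values; impute before construction")
  }
  if (min(dosages) < -1e-9 || max(dosages) > 2 + 1e-9) {
    data_error("dosages must lie in [0, 2]")
  }
  chrom <- as.character(chrom %||% rep("1", m))
  pos <- as.integer(pos %||% seq_len(m))
  if (length(chrom) != m || length(pos) != m) {
    data_error("chrom and pos must have one entry per marker")
  }
  if (any(pos < 1L)) data_error("positions must be strictly positive")
  ord <- order(chrom, pos)
  g <- list(
    dosages = dosages[, ord, drop = FALSE],
    map = data.frame(
      marker_id = colnames(dosages)[ord],
      chrom = chrom[ord],
      pos = pos[ord],
      stringsAsFactors = FALSE
    )
  )
  class(g) <- "permlmm_genotype"
  g
}

#' @export
print.permlmm_genotype <- function(x, ...) {
  cat(sprintf(
    "permlmm genotype: %d samples x %d markers on %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom))
  ))
  invisible(x)
}

#' @export
dim.permlmm_genotype <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a `permlmm_genotype`.
#' @param i sample selector (names, indices or logical).
#' @param j marker selector.
#' @param ... ignored.
#' @return A `permlmm_genotype` restricted to the selected samples/markers.
#' @export
`[.permlmm_genotype` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  d <- x$dosages[i, j, drop = FALSE]
  if (is.character(j)) j <- match(j, x$map$marker_id)
  if (is.logical(j)) j <- which(j)
  g <- list(dosages = d, map = x$map[j, , drop = FALSE])
  rownames(g$map) <- NULL
  class(g) <- "permlmm_genotype"
  g
}

sample_ids <- function(g) rownames(g$dosages)

#' Per-marker allele frequency and minor allele frequency
#'
#' @param g a `permlmm_genotype`.
#' @return `marker_freq`: the frequency of the counted allele per marker;
#'   `marker_maf`: the minor allele frequency `min(p, 1 - p)`.
#' @export
marker_freq <- function(g) colMeans(g$dosages) / 2

#' @rdname marker_freq
#' @export
marker_maf <- function(g) {
  p <- marker_freq(g)
  pmin(p, 1 - p)
}

# mean-impute missing dosages per marker (used by readers, never exported
# state: constructors reject NA)
impute_mean <- function(dosages) {
  nmiss <- sum(is.na(dosages))
  if (nmiss > 0L) {
    mu <- colMeans(dosages, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- mu[idx[, 2L]]
    log_msg("mean-imputed %d missing genotype call(s)", nmiss)
  }
  dosages
}
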