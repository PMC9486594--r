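# PLINK 1.9 bed/bim/fam reading and writing.
#
# .bed layout (SNP-major): 3 magic bytes 0x6c 0x1b 0x01, then ceil(n/4)
# bytes per marker, 2 bits per sample starting at the least significant
# pair: 00 = homozygous A1 (dosage 2), 10 = heterozygous (1),
# 11 = homozygous A2 (0), 01 = missing.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: dosage of A1 for each 2-bit code inside a byte
bed_byte_lut <- local({
  lut <- matrix(NA_real_, nrow = 256, ncol = 4)
  code_dose <- c(2, NA, 1, 0) # codes 0b00, 0b01, 0b10, 0b11
  for (b in 0:255) {
    for (s in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * s), 3L)
      lut[b + 1L, s + 1L] <- code_dose[code + 1L]
    }
  }
  lut
})

plink_paths <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  list(
    bed = paste0(prefix, ".bed"),
    bim = paste0(prefix, ".bim"),
    fam = paste0(prefix, ".fam")
  )
}

read_fam <- function(path) {
  if (!file.exists(path)) data_error(sprintf("fam file not found: %s", path))
  fam <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(fam) < 2L) data_error("fam file needs at least FID and IID columns")
  fam[[2L]]
}

read_bim <- function(path) {
  if (!file.exists(path)) data_error(sprintf("bim file not found: %s", path))
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) {
    data_error(sprintf("bim file lists no markers: %s", path))
  }
  bim <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "marker_id", "cm", "pos",
                                  "a1", "a2"))
  if (nrow(bim) < 1L) data_error("bim file lists no markers")
  bim
}

# Read dosages (of allele A1) for markers `marker_idx` (default all).
# Returns an n x length(marker_idx) matrix, possibly with NAs for missing
# calls; no flipping or imputation here.
read_bed_dosages <- function(bed_path, n, m, marker_idx = seq_len(m)) {
  if (!file.exists(bed_path)) {
    data_error(sprintf("bed file not found: %s", bed_path))
  }
  bpm <- ceiling(n / 4) # bytes per marker
  con <- file(bed_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (length(magic) != 3L || !identical(magic, BED_MAGIC)) {
    data_error("not a SNP-major PLINK .bed file (bad magic bytes)")
  }
  expected <- 3 + as.numeric(bpm) * m
  actual <- file.info(bed_path)$size
  if (actual != expected) {
    data_error(sprintf(
      "bed file size %d inconsistent with %d samples x %d markers",
      actual, n, m
    ))
  }
  out <- matrix(NA_real_, nrow = n, ncol = length(marker_idx))
  # contiguous runs can be read in one gulp
  runs <- split(marker_idx, cumsum(c(TRUE, diff(marker_idx) != 1L)))
  col0 <- 0L
  for (run in runs) {
    seek(con, where = 3 + (run[1L] - 1) * bpm, origin = "start")
    bytes <- readBin(con, "raw", bpm * length(run))
    ints <- as.integer(bytes) + 1L
    # decode: per byte 4 sample slots
    dos <- bed_byte_lut[ints, , drop = FALSE] # (bpm*q) x 4
    dos <- matrix(t(dos), nrow = 4L * bpm)    # (4*bpm) x q, sample-fast
    out[, col0 + seq_along(run)] <- dos[seq_len(n), , drop = FALSE]
    col0 <- col0 + length(run)
  }
  out
}

#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' Hard calls only: dosages must be 0, 1 or 2. Dosage is written as the
#' count of allele A1.
#'
#' @param g a `permlmm_genotype`.
#' @param prefix output path prefix (".bed"/".bim"/".fam" appended).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(g, prefix) {
  d <- g$dosages
  if (any(abs(d - round(d)) > 1e-9)) {
    data_error("PLINK bed stores hard calls; dosages must be 0/1/2")
  }
  d <- round(d)
  p <- plink_paths(prefix)
  n <- nrow(d)
  m <- ncol(d)
  fam <- data.frame(fid = rownames(d), iid = rownames(d),
                    pat = 0L, mat = 0L, sex = 0L, phe = -9L)
  write.table(fam, p$fam, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = " ")
  bim <- data.frame(chrom = g$map$chrom, marker_id = g$map$marker_id,
                    cm = 0L, pos = g$map$pos, a1 = "A", a2 = "T")
  write.table(bim, p$bim, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11
  code_of <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  bpm <- ceiling(n / 4)
  con <- file(p$bed, "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  pad <- 4L * bpm - n
  for (j in seq_len(m)) {
    codes <- c(code_of[as.character(d[, j])], rep(0L, pad))
    quads <- matrix(codes, nrow = 4L)
    bytes <- as.raw(quads[1L, ] + bitwShiftL(quads[2L, ], 2L) +
                      bitwShiftL(quads[3L, ], 4L) + bitwShiftL(quads[4L, ], 6L))
    writeBin(bytes, con)
  }
  invisible(prefix)
}

# Full PLINK read: flips each marker so dosage counts the minor allele,
# then mean-imputes missing calls.
read_plink_genotype <- function(prefix) {
  p <- plink_paths(prefix)
  ids <- read_fam(p$fam)
  bim <- read_bim(p$bim)
  n <- length(ids)
  m <- nrow(bim)
  d <- read_bed_dosages(p$bed, n, m)
  d <- flip_to_minor(d)
  d <- impute_mean(d)
  rownames(d) <- ids
  colnames(d) <- bim$marker_id
  genotype_matrix(d, chrom = as.character(bim$chrom), pos = bim$pos)
}

# flip columns so that dosage counts the minor allele (freq <= 0.5)
flip_to_minor <- function(d) {
  p <- colMeans(d, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  d
}
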