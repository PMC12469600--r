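## PLINK 1 binary (bed/bim/fam) reader and writer, SNP-major layout.
## Two-bit codes per genotype: 00 = homozygous A1, 01 = missing,
## 10 = heterozygous, 11 = homozygous A2; four genotypes per byte,
## least-significant bits first.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_SNP_MAJOR <- as.raw(0x01)

## lookup: byte value (0..255) -> 4 A1-allele dosages
.bed_decode_lut <- local({
  lut <- matrix(NA_integer_, nrow = 4L, ncol = 256L)
  code_to_dosage <- c(2L, NA_integer_, 1L, 0L)  # codes 0,1,2,3
  for (b in 0:255) {
    codes <- bitwAnd(bitwShiftR(b, 2L * (0:3)), 3L)
    lut[, b + 1L] <- code_to_dosage[codes + 1L]
  }
  lut
})

#' Read a PLINK 1 binary fileset
#'
#' Reads `prefix.bed` / `.bim` / `.fam` (or three explicit paths) into a
#' [genotype_dataset()]. Dosages are counted on the minor allele as
#' observed in the data: if the bim A1 allele is in fact the major allele,
#' dosages are flipped and the allele columns swapped. A variant with
#' allele frequency exactly 0.5 (or no observed genotypes) keeps the bim
#' A1 allele as minor.
#'
#' Phenotype codes in the fam file map 2 to case, 1 to control, and 0 or
#' -9 to missing; sex codes map 1 to male, 2 to female, 0 to unknown.
#'
#' @param bed_path Path to the `.bed` file, or a prefix if the other two
#'   paths are omitted.
#' @param bim_path,fam_path Paths to the `.bim` and `.fam` files; derived
#'   from `bed_path` by extension substitution when `NULL`.
#' @return A [genotype_dataset()].
#' @export
read_plink <- function(bed_path, bim_path = NULL, fam_path = NULL) {
  if (is.null(bim_path) && is.null(fam_path) && !grepl("\\.bed$", bed_path)) {
    bim_path <- paste0(bed_path, ".bim")
    fam_path <- paste0(bed_path, ".fam")
    bed_path <- paste0(bed_path, ".bed")
  }
  if (is.null(bim_path)) bim_path <- sub("\\.bed$", ".bim", bed_path)
  if (is.null(fam_path)) fam_path <- sub("\\.bed$", ".fam", bed_path)
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }

  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "phen"))
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chr", "id", "cm", "bp", "a1", "a2"))
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:2], BED_MAGIC)) {
    stop("bed format error: bad magic bytes in ", bed_path)
  }
  if (raw[3] != BED_SNP_MAJOR) {
    stop("bed format error: only SNP-major (mode 0x01) files are supported")
  }
  nb <- ceiling(n / 4)
  if (length(raw) != 3L + nb * m) {
    stop("bed consistency error: expected ", 3L + nb * m, " bytes for ",
         n, " samples x ", m, " variants, found ", length(raw))
  }

  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  if (m > 0L && n > 0L) {
    body <- as.integer(raw[-(1:3)])
    # decode all bytes at once: 4 dosages per byte, column-per-variant
    all_dos <- .bed_decode_lut[, body + 1L]
    dim(all_dos) <- c(4L * nb, m)
    geno <- all_dos[seq_len(n), , drop = FALSE]
  }

  sex <- c("unknown", "male", "female")[match(fam$sex, c(0, 1, 2), nomatch = 1L)]
  phen <- rep("missing", n)
  phen[fam$phen == 2] <- "case"
  phen[fam$phen == 1] <- "control"

  samples <- data.frame(sample_id = as.character(fam$iid), sex = sex,
                        phenotype = phen, stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = as.character(bim$id),
                         chromosome = as.character(bim$chr),
                         bp = as.integer(bim$bp),
                         allele_minor = as.character(bim$a1),
                         allele_major = as.character(bim$a2),
                         stringsAsFactors = FALSE)

  ds <- genotype_dataset(geno, samples, variants)
  recompute_minor_allele(ds)
}

#' Re-orient dosages onto the observed minor allele
#'
#' For each variant, if the allele currently counted has observed
#' frequency above 0.5 the dosages are flipped (d becomes 2 - d) and the
#' allele labels swapped. Exact ties and all-missing variants keep the
#' current orientation.
#'
#' @param x A [genotype_dataset()].
#' @return The re-oriented dataset.
#' @export
recompute_minor_allele <- function(x) {
  g <- x$genotypes
  cnt <- colSums(g, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(g))
  flip <- tot > 0L & cnt / pmax(tot, 1L) > 0.5
  if (any(flip)) {
    g[, flip] <- 2L - g[, flip, drop = FALSE]
    tmp <- x$variants$allele_minor[flip]
    x$variants$allele_minor[flip] <- x$variants$allele_major[flip]
    x$variants$allele_major[flip] <- tmp
    x$genotypes <- g
  }
  x
}

#' Write a PLINK 1 binary fileset
#'
#' Writes `prefix.bed` (SNP-major), `prefix.bim` and `prefix.fam`. The
#' minor allele is written as A1, so `read_plink(write_plink(d))` returns
#' a dataset identical to `d`.
#'
#' @param dataset A [genotype_dataset()].
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  validate_genotype_dataset(dataset)
  if (n_variants(dataset) == 0L) stop("refusing to write a dataset with no variants")
  g <- dataset$genotypes
  n <- nrow(g)
  m <- ncol(g)
  nb <- ceiling(n / 4)

  # dosage -> 2-bit code (2 -> 00 hom A1, 1 -> 10 het, 0 -> 11 hom A2, NA -> 01)
  codes <- matrix(0L, nrow = 4L * nb, ncol = m)
  cd <- g
  cd[] <- ifelse(is.na(g), 1L, c(3L, 2L, 0L)[g + 1L])
  codes[seq_len(n), ] <- cd
  bytes <- codes[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] +
    4L * codes[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE] +
    16L * codes[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE] +
    64L * codes[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE]

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(BED_MAGIC, BED_SNP_MAJOR, as.raw(bytes)), con)

  sex_code <- c(male = 1L, female = 2L, unknown = 0L)[dataset$samples$sex]
  phen_code <- c(case = 2L, control = 1L, missing = -9L)[dataset$samples$phenotype]
  fam <- data.frame(dataset$samples$sample_id, dataset$samples$sample_id,
                    0L, 0L, sex_code, phen_code)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(dataset$variants$chromosome, dataset$variants$variant_id,
                    0, dataset$variants$bp, dataset$variants$allele_minor,
                    dataset$variants$allele_major)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
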