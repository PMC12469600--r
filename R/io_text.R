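## Plain-text genotype dialect: tab-separated, one row per individual.
## Columns: sample_id, sex, phenotype, then one column per variant id
## holding the minor-allele dosage (0/1/2) or NA. Readers and writers
## accept gzip-compressed files (".gz" suffix); reading auto-detects
## compression via the connection layer.

#' Write a genotype dataset as tab-separated text
#'
#' Variant metadata beyond the identifier (chromosome, position, alleles)
#' is not carried by this dialect; it exists for small deterministic
#' fixtures, while [write_plink()] is the lossless format.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_geno_text <- function(dataset, path) {
  validate_genotype_dataset(dataset)
  df <- data.frame(sample_id = dataset$samples$sample_id,
                   sex = dataset$samples$sex,
                   phenotype = dataset$samples$phenotype,
                   stringsAsFactors = FALSE)
  g <- as.data.frame(dataset$genotypes)
  names(g) <- dataset$variants$variant_id
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)
  utils::write.table(cbind(df, g), con, quote = FALSE, sep = "\t",
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read the tab-separated genotype dialect
#'
#' Variant metadata absent from the format is filled with defaults:
#' chromosome `"0"`, position equal to the column rank, alleles `"A"`
#' (minor) and `"B"` (major).
#'
#' @param path Input path (plain or gzip-compressed).
#' @return A [genotype_dataset()].
#' @export
read_geno_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path)  # transparently reads uncompressed text too
  df <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = "NA")
  fixed <- c("sample_id", "sex", "phenotype")
  if (!all(fixed %in% names(df)[1:3])) {
    stop("text dialect error: first columns must be ", paste(fixed, collapse = ", "))
  }
  vids <- setdiff(names(df), fixed)
  g <- as.matrix(df[, vids, drop = FALSE])
  storage.mode(g) <- "integer"
  samples <- data.frame(sample_id = as.character(df$sample_id),
                        sex = df$sex, phenotype = df$phenotype,
                        stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = vids, chromosome = "0",
                         bp = seq_along(vids), allele_minor = "A",
                         allele_major = "B", stringsAsFactors = FALSE)
  genotype_dataset(g, samples, variants)
}
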