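#' Construct a genotype dataset
#'
#' The core container of the package: a samples-by-variants matrix of
#' minor-allele dosages together with per-sample metadata (sex, phenotype)
#' and per-variant metadata (identifier, chromosome, position, alleles).
#'
#' @param genotypes Integer matrix, one row per sample and one column per
#'   variant. Entries are minor-allele dosages 0, 1 or 2, or `NA` for a
#'   missing call.
#' @param samples Data frame with columns `sample_id` (unique character),
#'   `sex` (one of `"male"`, `"female"`, `"unknown"`) and `phenotype`
#'   (one of `"case"`, `"control"`, `"missing"`).
#' @param variants Data frame with columns `variant_id` (unique character),
#'   `chromosome` (character), `bp` (integer 1-based position),
#'   `allele_minor` and `allele_major` (character).
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, samples, variants) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  obj <- structure(
    list(genotypes = genotypes, samples = samples, variants = variants),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(obj)
  rownames(obj$genotypes) <- samples$sample_id
  colnames(obj$genotypes) <- variants$variant_id
  obj
}

#' Validate a genotype dataset
#'
#' Checks the class invariants: matrix dimensions match the metadata,
#' all non-missing dosages are in \{0, 1, 2\}, and identifiers are unique.
#'
#' @param x A `genotype_dataset`.
#' @return `x`, invisibly. Errors if any invariant is violated.
#' @export
validate_genotype_dataset <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  g <- x$genotypes
  if (nrow(g) != nrow(x$samples)) {
    stop("genotype rows (", nrow(g), ") != sample count (", nrow(x$samples), ")")
  }
  if (ncol(g) != nrow(x$variants)) {
    stop("genotype columns (", ncol(g), ") != variant count (", nrow(x$variants), ")")
  }
  req_s <- c("sample_id", "sex", "phenotype")
  req_v <- c("variant_id", "chromosome", "bp", "allele_minor", "allele_major")
  if (!all(req_s %in% names(x$samples))) {
    stop("samples must have columns: ", paste(req_s, collapse = ", "))
  }
  if (!all(req_v %in% names(x$variants))) {
    stop("variants must have columns: ", paste(req_v, collapse = ", "))
  }
  if (anyDuplicated(x$samples$sample_id)) stop("duplicate sample_id")
  if (anyDuplicated(x$variants$variant_id)) stop("duplicate variant_id")
  bad_sex <- setdiff(unique(x$samples$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) stop("invalid sex codes: ", paste(bad_sex, collapse = ", "))
  bad_ph <- setdiff(unique(x$samples$phenotype), c("case", "control", "missing"))
  if (length(bad_ph)) stop("invalid phenotypes: ", paste(bad_ph, collapse = ", "))
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("non-missing dosages must be 0, 1 or 2")
  }
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  ph <- table(factor(x$samples$phenotype, c("case", "control", "missing")))
  sx <- table(factor(x$samples$sex, c("male", "female", "unknown")))
  cat("genotype_dataset: ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes), " variants\n", sep = "")
  cat("  phenotype: ", ph[["case"]], " case / ", ph[["control"]], " control / ",
      ph[["missing"]], " missing\n", sep = "")
  cat("  sex:       ", sx[["male"]], " male / ", sx[["female"]], " female / ",
      sx[["unknown"]], " unknown\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  cat("  missing genotype rate: ", signif(miss, 3), "\n", sep = "")
  invisible(x)
}

#' Number of samples in a dataset
#' @param x A `genotype_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$genotypes)

#' Number of variants in a dataset
#' @param x A `genotype_dataset`.
#' @return Integer count.
#' @export
n_variants <- function(x) ncol(x$genotypes)

#' Subset a dataset by variant
#'
#' @param x A `genotype_dataset`.
#' @param keep Logical, integer or character index into the variants.
#' @return A `genotype_dataset` restricted to the selected variants.
#' @export
subset_variants <- function(x, keep) {
  if (is.character(keep)) keep <- match(keep, x$variants$variant_id)
  genotype_dataset(
    x$genotypes[, keep, drop = FALSE],
    x$samples,
    x$variants[keep, , drop = FALSE]
  )
}

#' Subset a dataset by sample
#'
#' @param x A `genotype_dataset`.
#' @param keep Logical, integer or character index into the samples.
#' @return A `genotype_dataset` restricted to the selected samples.
#' @export
subset_samples <- function(x, keep) {
  if (is.character(keep)) keep <- match(keep, x$samples$sample_id)
  genotype_dataset(
    x$genotypes[keep, , drop = FALSE],
    x$samples[keep, , drop = FALSE],
    x$variants
  )
}

#' Split a cohort into male and female datasets
#'
#' Sex-stratified analysis treats the two sexes as independent datasets.
#' Both outputs retain every variant; no per-sex re-filtering happens at
#' split time. Samples of unknown sex are excluded from both outputs.
#'
#' @param x A `genotype_dataset`.
#' @return A list with elements `male` and `female`, each a
#'   `genotype_dataset`.
#' @export
split_by_sex <- function(x) {
  validate_genotype_dataset(x)
  m <- x$samples$sex == "male"
  f <- x$samples$sex == "female"
  if (!any(m)) warning("no male samples; returning empty male dataset")
  if (!any(f)) warning("no female samples; returning empty female dataset")
  list(male = subset_samples(x, which(m)), female = subset_samples(x, which(f)))
}

## Internal: 0/1 case indicator (NA for missing phenotype)
case_indicator <- function(x) {
  ifelse(x$samples$phenotype == "case", 1L,
         ifelse(x$samples$phenotype == "control", 0L, NA_integer_))
}
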