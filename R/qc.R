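## Variant quality control: a fixed sequence of per-variant filters
## (missing call rate, monomorphy, Hardy-Weinberg in controls, minor
## allele frequency) followed by windowed VIF-based LD pruning.

#' Remove variants with a high missing call rate
#'
#' A variant is removed when its fraction of missing calls strictly
#' exceeds `max_missing_rate`.
#'
#' @param dataset A [genotype_dataset()].
#' @param max_missing_rate Maximum tolerated missing rate (default 0.10).
#' @return A list with `dataset` (filtered) and `removed_ids`.
#' @export
filter_callrate <- function(dataset, max_missing_rate = 0.10) {
  miss <- colMeans(is.na(dataset$genotypes))
  drop <- miss > max_missing_rate
  list(dataset = subset_variants(dataset, !drop),
       removed_ids = dataset$variants$variant_id[drop])
}

#' Remove monomorphic variants
#'
#' A variant is monomorphic when all its non-missing dosages are equal
#' (no observed heterozygote or alternative homozygote). Variants with
#' zero non-missing calls are also removed here.
#'
#' @param dataset A [genotype_dataset()].
#' @return A list with `dataset` and `removed_ids`.
#' @export
filter_monomorphic <- function(dataset) {
  g <- dataset$genotypes
  nvals <- apply(g, 2, function(d) length(unique(d[!is.na(d)])))
  drop <- nvals <= 1L
  list(dataset = subset_variants(dataset, !drop),
       removed_ids = dataset$variants$variant_id[drop])
}

#' Remove variants violating Hardy-Weinberg proportions
#'
#' Applies [hwe_exact_test()] per variant, by default among controls
#' only (cases may legitimately depart from Hardy-Weinberg at associated
#' loci), and removes variants with p-value strictly below `alpha`.
#'
#' @param dataset A [genotype_dataset()].
#' @param alpha Significance threshold (default 1e-3).
#' @param use_controls_only Test in controls only (default TRUE).
#' @return A list with `dataset` and `removed_ids`.
#' @export
filter_hwe <- function(dataset, alpha = 1e-3, use_controls_only = TRUE) {
  rows <- if (use_controls_only) {
    which(dataset$samples$phenotype == "control")
  } else {
    seq_len(n_samples(dataset))
  }
  if (use_controls_only && length(rows) == 0L) {
    stop("filter_hwe: no controls in dataset")
  }
  p <- hwe_pvalues(dataset$genotypes[rows, , drop = FALSE])
  drop <- !is.na(p) & p < alpha
  list(dataset = subset_variants(dataset, !drop),
       removed_ids = dataset$variants$variant_id[drop])
}

#' Remove low-frequency variants
#'
#' Minor allele frequency is the minor-allele count divided by twice the
#' number of non-missing genotypes, folded to `min(f, 1 - f)`. Variants
#' with MAF strictly below `min_maf` are removed.
#'
#' @param dataset A [genotype_dataset()].
#' @param min_maf Minimum MAF retained (default 0.01).
#' @return A list with `dataset` and `removed_ids`.
#' @export
filter_maf <- function(dataset, min_maf = 0.01) {
  maf <- variant_maf(dataset)
  drop <- maf < min_maf
  list(dataset = subset_variants(dataset, !drop),
       removed_ids = dataset$variants$variant_id[drop])
}

#' Per-variant folded minor allele frequency
#'
#' @param dataset A [genotype_dataset()].
#' @return Numeric vector of MAFs (0 for all-missing variants).
#' @export
variant_maf <- function(dataset) {
  g <- dataset$genotypes
  cnt <- colSums(g, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(g))
  f <- ifelse(tot > 0, cnt / tot, 0)
  pmin(f, 1 - f)
}

## VIF (1 / (1 - R^2)) of each column of X regressed on the others.
## X must be complete (impute first); constant columns get VIF 1.
window_vifs <- function(X) {
  w <- ncol(X)
  vapply(seq_len(w), function(i) {
    y <- X[, i]
    tss <- sum((y - mean(y))^2)
    if (tss == 0 || w == 1L) return(1)
    Z <- cbind(1, X[, -i, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    1 / max(1 - r2, 1e-12)
  }, numeric(1))
}

## iteratively drop the max-VIF variant inside one window; returns the
## retained subset of idx (ties on VIF drop the larger variant index)
prune_window <- function(geno, idx, vif_threshold) {
  keep <- idx
  while (length(keep) >= 2L) {
    X <- geno[, keep, drop = FALSE]
    # mean-impute missing dosages within the window for the regression
    for (j in seq_len(ncol(X))) {
      mj <- is.na(X[, j])
      if (any(mj)) X[mj, j] <- mean(X[, j], na.rm = TRUE)
      if (anyNA(X[, j])) X[, j] <- 0  # all-missing column
    }
    vifs <- window_vifs(X)
    mx <- max(vifs)
    if (mx <= vif_threshold) break
    worst <- max(which(vifs >= mx * (1 - 1e-9)))
    keep <- keep[-worst]
  }
  keep
}

#' Windowed VIF-based LD pruning
#'
#' Slides a window of `window` variants along each chromosome, advancing
#' by `step` variants. Within a window, each variant's variance inflation
#' factor VIF = 1 / (1 - R^2) is computed from the multiple regression of
#' its dosage on the other retained variants in the window (missing
#' dosages mean-imputed within the window); while any VIF exceeds
#' `vif_threshold` the variant with the largest VIF is removed (ties
#' remove the larger variant index). Sweeps repeat until no variant is
#' removed, so the operation is idempotent. Windows never span
#' chromosomes.
#'
#' @param dataset A [genotype_dataset()] with variants sorted by
#'   (chromosome, bp).
#' @param window Window size in variants (default 50).
#' @param step Window increment in variants (default 5).
#' @param vif_threshold Maximum tolerated VIF (default 2.0).
#' @return A list with `dataset` and `removed_ids`.
#' @export
ld_prune_vif <- function(dataset, window = 50, step = 5, vif_threshold = 2.0) {
  if (window < 2) stop("ld_prune_vif: window must be at least 2")
  if (step < 1) stop("ld_prune_vif: step must be at least 1")
  g <- dataset$genotypes
  removed <- character(0)

  for (chr in unique(dataset$variants$chromosome)) {
    retained <- which(dataset$variants$chromosome == chr)
    repeat {
      dropped_this_pass <- FALSE
      i <- 1L
      while (i <= length(retained)) {
        idx <- retained[i:min(i + window - 1L, length(retained))]
        if (length(idx) >= 2L) {
          kept <- prune_window(g, idx, vif_threshold)
          gone <- setdiff(idx, kept)
          if (length(gone)) {
            dropped_this_pass <- TRUE
            removed <- c(removed, dataset$variants$variant_id[gone])
            retained <- setdiff(retained, gone)
          }
        }
        i <- i + step
      }
      if (!dropped_this_pass) break
    }
  }
  keep <- !(dataset$variants$variant_id %in% removed)
  list(dataset = subset_variants(dataset, keep), removed_ids = removed)
}

#' Run the full variant QC chain
#'
#' Applies, in order: missing call rate, monomorphy, Hardy-Weinberg in
#' controls, minor allele frequency, and LD pruning. A variant failing
#' several criteria is attributed to the first filter that removes it.
#'
#' @param dataset A [genotype_dataset()].
#' @param max_missing_rate,min_maf,hwe_alpha,hwe_controls_only,window,step,vif_threshold
#'   Filter parameters; see the individual filter functions.
#' @param prune Apply LD pruning (default TRUE).
#' @return A list with `dataset` (the retained variants) and `report`,
#'   a `qc_report` object tallying removals per stage.
#' @export
run_qc <- function(dataset, max_missing_rate = 0.10, min_maf = 0.01,
                   hwe_alpha = 1e-3, hwe_controls_only = TRUE,
                   window = 50, step = 5, vif_threshold = 2.0,
                   prune = TRUE) {
  validate_genotype_dataset(dataset)
  n_input <- n_variants(dataset)
  log <- data.frame(variant_id = character(0), stage = character(0),
                    stringsAsFactors = FALSE)
  note <- function(ids, stage) {
    if (length(ids)) rbind(log, data.frame(variant_id = ids, stage = stage,
                                           stringsAsFactors = FALSE)) else log
  }

  s1 <- filter_callrate(dataset, max_missing_rate)
  log <- note(s1$removed_ids, "callrate")
  s2 <- filter_monomorphic(s1$dataset)
  log <- note(s2$removed_ids, "monomorphic")
  s3 <- filter_hwe(s2$dataset, hwe_alpha, hwe_controls_only)
  log <- note(s3$removed_ids, "hwe")
  s4 <- filter_maf(s3$dataset, min_maf)
  log <- note(s4$removed_ids, "maf")
  if (prune) {
    s5 <- ld_prune_vif(s4$dataset, window, step, vif_threshold)
    log <- note(s5$removed_ids, "pruning")
    out <- s5$dataset
  } else {
    out <- s4$dataset
  }

  report <- structure(list(
    n_input = n_input,
    n_removed_callrate = length(s1$removed_ids),
    n_removed_monomorphic = length(s2$removed_ids),
    n_removed_hwe = length(s3$removed_ids),
    n_removed_maf = length(s4$removed_ids),
    n_removed_pruning = if (prune) length(s5$removed_ids) else 0L,
    n_retained = n_variants(out),
    removal_log = log
  ), class = "qc_report")
  stopifnot(report$n_input - sum(unlist(report[2:6])) == report$n_retained)
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("variant QC report\n")
  cat(sprintf("  %-22s %d\n", "input variants", x$n_input))
  cat(sprintf("  %-22s %d\n", "removed: call rate", x$n_removed_callrate))
  cat(sprintf("  %-22s %d\n", "removed: monomorphic", x$n_removed_monomorphic))
  cat(sprintf("  %-22s %d\n", "removed: HWE", x$n_removed_hwe))
  cat(sprintf("  %-22s %d\n", "removed: MAF", x$n_removed_maf))
  cat(sprintf("  %-22s %d\n", "removed: LD pruning", x$n_removed_pruning))
  cat(sprintf("  %-22s %d\n", "retained", x$n_retained))
  invisible(x)
}

#' Serialize a QC report as two TSV files
#'
#' Writes `<prefix>.qc_summary.tsv` (one row per stage) and
#' `<prefix>.qc_removals.tsv` (variant_id, stage).
#'
#' @param report A `qc_report`.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_qc_report <- function(report, prefix) {
  summ <- data.frame(
    stage = c("input", "callrate", "monomorphic", "hwe", "maf", "pruning", "retained"),
    n = c(report$n_input, report$n_removed_callrate, report$n_removed_monomorphic,
          report$n_removed_hwe, report$n_removed_maf, report$n_removed_pruning,
          report$n_retained)
  )
  p1 <- paste0(prefix, ".qc_summary.tsv")
  p2 <- paste0(prefix, ".qc_removals.tsv")
  utils::write.table(summ, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$removal_log, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
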