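## Allelic association: per-variant 2x2 allele-count tables in cases vs
## controls, odds-ratio ranking, the polygenic score, and a max-T
## phenotype-permutation test.

#' Allelic odds ratio from a 2x2 allele-count table
#'
#' OR = (minor_case * major_control) / (major_case * minor_control). If
#' any cell is zero, 0.5 is added to all four cells (Haldane-Anscombe
#' continuity correction) before computing, so the result is always
#' finite and positive.
#'
#' @param minor_case,major_case,minor_control,major_control Allele counts
#'   (vectors are accepted and processed elementwise).
#' @return A list with `odds_ratio` and `log_or` (natural log).
#' @export
allelic_odds_ratio <- function(minor_case, major_case, minor_control,
                               major_control) {
  if (any(c(minor_case, major_case, minor_control, major_control) < 0)) {
    stop("allele counts must be non-negative")
  }
  if (any(minor_case + major_case == 0)) {
    stop("case group has zero observed alleles")
  }
  if (any(minor_control + major_control == 0)) {
    stop("control group has zero observed alleles")
  }
  zero <- minor_case == 0 | major_case == 0 | minor_control == 0 |
    major_control == 0
  a <- minor_case + 0.5 * zero
  b <- major_case + 0.5 * zero
  c_ <- minor_control + 0.5 * zero
  d <- major_control + 0.5 * zero
  or <- (a * d) / (b * c_)
  list(odds_ratio = or, log_or = log(or))
}

#' Per-variant allele counts by phenotype
#'
#' @param dataset A [genotype_dataset()]. Samples with missing phenotype
#'   are ignored.
#' @return A data frame with one row per variant: `variant_id`,
#'   `minor_case`, `major_case`, `minor_control`, `major_control`.
#' @export
variant_counts <- function(dataset) {
  g <- dataset$genotypes
  is_case <- dataset$samples$phenotype == "case"
  is_ctrl <- dataset$samples$phenotype == "control"
  gc <- g[is_case, , drop = FALSE]
  gt <- g[is_ctrl, , drop = FALSE]
  minor_case <- colSums(gc, na.rm = TRUE)
  minor_control <- colSums(gt, na.rm = TRUE)
  major_case <- 2L * colSums(!is.na(gc)) - minor_case
  major_control <- 2L * colSums(!is.na(gt)) - minor_control
  data.frame(variant_id = dataset$variants$variant_id,
             minor_case = as.integer(minor_case),
             major_case = as.integer(major_case),
             minor_control = as.integer(minor_control),
             major_control = as.integer(major_control),
             stringsAsFactors = FALSE)
}

#' Rank variants by allelic odds ratio
#'
#' Computes each variant's allelic odds ratio and sorts. The default key
#' is the raw odds ratio, descending, so the top of the list holds the
#' most predictive risk variants; `ranking_key = "abs_log_or"` ranks by
#' the magnitude of the log odds ratio instead, which also surfaces
#' protective variants (OR well below 1). Ties preserve the original
#' variant order.
#'
#' @param dataset A [genotype_dataset()] with at least one case and one
#'   control.
#' @param ranking_key `"or_descending"` (default) or `"abs_log_or"`.
#' @return A data frame of per-variant statistics sorted by rank:
#'   allele counts, `maf`, `odds_ratio`, `log_or`, `rank`.
#' @export
rank_variants <- function(dataset, ranking_key = c("or_descending", "abs_log_or")) {
  ranking_key <- match.arg(ranking_key)
  if (!any(dataset$samples$phenotype == "case")) stop("no cases in dataset")
  if (!any(dataset$samples$phenotype == "control")) stop("no controls in dataset")
  st <- variant_counts(dataset)
  or <- allelic_odds_ratio(st$minor_case, st$major_case,
                           st$minor_control, st$major_control)
  st$odds_ratio <- or$odds_ratio
  st$log_or <- or$log_or
  st$maf <- variant_maf(dataset)
  rank_variant_stats(st, ranking_key)
}

## sort a VariantStats data frame by the ranking key; stable in the
## original row order so ties are deterministic
rank_variant_stats <- function(st, ranking_key = "or_descending") {
  key <- if (ranking_key == "abs_log_or") abs(st$log_or) else st$odds_ratio
  ord <- order(-key, seq_len(nrow(st)))
  st <- st[ord, , drop = FALSE]
  st$rank <- seq_len(nrow(st))
  rownames(st) <- NULL
  st
}

#' Compute allelic polygenic risk scores
#'
#' For individual j and N selected variants, the score is
#' \deqn{PRS_j = \sum_i \log(OR_i) \, g_{ij} / (2N)}
#' where the sum runs over the individual's non-missing genotypes among
#' the selected variants. With `denominator_mode = "per_individual"`
#' (default) N is replaced by the count of non-missing selected variants
#' for that individual, so missing calls do not deflate scores;
#' `"fixed"` always divides by the full selection size. The log is
#' natural; the base only rescales all scores by a constant and cannot
#' change any percentile-based classification.
#'
#' @param dataset A [genotype_dataset()].
#' @param selected_stats Data frame with columns `variant_id` and
#'   `log_or` (typically the head of [rank_variants()] output).
#' @param denominator_mode `"per_individual"` (default) or `"fixed"`.
#' @return A data frame (`score_profile`): `sample_id`, `phenotype`,
#'   `score` (NA when every selected genotype is missing), with
#'   attributes `n_variants` and `variant_ids`.
#' @export
compute_prs <- function(dataset, selected_stats,
                        denominator_mode = c("per_individual", "fixed")) {
  denominator_mode <- match.arg(denominator_mode)
  vids <- selected_stats$variant_id
  if (length(vids) < 1L) stop("at least one variant must be selected")
  idx <- match(vids, dataset$variants$variant_id)
  if (anyNA(idx)) {
    stop("selected variants absent from dataset: ",
         paste(utils::head(vids[is.na(idx)], 5), collapse = ", "))
  }
  g <- dataset$genotypes[, idx, drop = FALSE]
  w <- selected_stats$log_or
  obs <- !is.na(g)
  g0 <- g
  g0[!obs] <- 0L
  num <- as.numeric(g0 %*% w)
  n_eff <- if (denominator_mode == "fixed") {
    rep(length(vids), nrow(g))
  } else {
    rowSums(obs)
  }
  score <- ifelse(rowSums(obs) == 0L, NA_real_, num / (2 * pmax(n_eff, 1L)))
  out <- data.frame(sample_id = dataset$samples$sample_id,
                    phenotype = dataset$samples$phenotype,
                    score = score, stringsAsFactors = FALSE)
  attr(out, "n_variants") <- length(vids)
  attr(out, "variant_ids") <- vids
  class(out) <- c("score_profile", "data.frame")
  out
}

## Pearson chi-square of the 2x2 allelic table, vectorized over variants.
## Zero margins give statistic 0.
allelic_chisq <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- ifelse(den > 0, n * (a * d - b * c_)^2 / den, 0)
  as.numeric(stat)
}

#' Max-T phenotype permutation test for single-variant association
#'
#' The per-variant statistic is the Pearson chi-square of the 2x2 allele
#' count table (cases vs controls). The null distribution is generated
#' by permuting phenotype labels over individuals; the family-wise
#' adjusted p-value of variant i is the proportion of permutations whose
#' maximum statistic across all variants reaches the observed statistic
#' of i (max-T). The add-one estimator (r + 1) / (n_perms + 1) keeps
#' p-values strictly positive.
#'
#' @param dataset A [genotype_dataset()] with both phenotypes present.
#' @param n_perms Number of permutations (default 100000).
#' @param seed Integer seed; required, logged in the result.
#' @return A data frame: `variant_id`, `statistic`, `p_adjusted`, with
#'   attributes `n_perms` and `seed`.
#' @export
permutation_test <- function(dataset, n_perms = 100000, seed) {
  if (missing(seed)) stop("permutation_test: seed is required")
  if (n_perms < 1) stop("n_perms must be at least 1")
  ph <- case_indicator(dataset)
  use <- which(!is.na(ph))
  ph <- ph[use]
  if (length(unique(ph)) < 2L) stop("phenotype is constant; cannot permute")
  g <- dataset$genotypes[use, , drop = FALSE]
  obs_mat <- !is.na(g)
  g0 <- g
  g0[!obs_mat] <- 0L
  storage.mode(g0) <- "double"
  obs_num <- obs_mat
  storage.mode(obs_num) <- "double"

  tot_minor <- colSums(g0)
  tot_obs <- colSums(obs_num)

  stat_for <- function(z) {
    # z: 0/1 case indicator over rows; returns per-variant chi-square
    a <- as.numeric(crossprod(g0, z))
    obs_case <- as.numeric(crossprod(obs_num, z))
    b <- 2 * obs_case - a
    c_ <- tot_minor - a
    d <- 2 * (tot_obs - obs_case) - c_
    allelic_chisq(a, b, c_, d)
  }

  observed <- stat_for(as.numeric(ph))
  set.seed(seed)
  count_ge <- numeric(ncol(g))
  # batched permutations: each column of Z is one permuted case indicator
  batch <- 256L
  done <- 0L
  while (done < n_perms) {
    nb <- min(batch, n_perms - done)
    Z <- vapply(seq_len(nb), function(i) as.numeric(sample(ph)),
                numeric(length(ph)))
    A <- crossprod(g0, Z)
    OC <- crossprod(obs_num, Z)
    B <- 2 * OC - A
    C_ <- tot_minor - A
    D <- 2 * (tot_obs - OC) - C_
    N <- A + B + C_ + D
    DEN <- (A + B) * (C_ + D) * (A + C_) * (B + D)
    S <- ifelse(DEN > 0, N * (A * D - B * C_)^2 / DEN, 0)
    maxs <- apply(S, 2, max)
    count_ge <- count_ge + vapply(observed, function(o) sum(maxs >= o),
                                  numeric(1))
    done <- done + nb
  }
  p_adj <- (count_ge + 1) / (n_perms + 1)
  out <- data.frame(variant_id = dataset$variants$variant_id,
                    statistic = observed, p_adjusted = p_adj,
                    stringsAsFactors = FALSE)
  attr(out, "n_perms") <- n_perms
  attr(out, "seed") <- seed
  out
}

#' Write a ranked variant-statistics table as TSV
#'
#' @param stats Output of [rank_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_stats <- function(stats, path) {
  cols <- c("variant_id", "minor_case", "major_case", "minor_control",
            "major_control", "maf", "odds_ratio", "log_or", "rank")
  utils::write.table(stats[, intersect(cols, names(stats))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a score profile as TSV
#'
#' Columns sample_id, phenotype, score -- column-compatible with the
#' .profile output of PLINK's --score.
#'
#' @param profile Output of [compute_prs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
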