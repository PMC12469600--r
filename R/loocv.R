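## Leave-one-out cross-validation: every individual is predicted by a
## classification rule rebuilt from scratch (allele counts, odds-ratio
## ranking, variant selection, scores, control-score threshold) on the
## other K - 1 individuals. Allele counts are maintained incrementally,
## which makes the K refits cheap while remaining exactly equal to a
## from-scratch refit (integer arithmetic throughout).

#' Configuration for leave-one-out cross-validation
#'
#' @param n_variants Number of top-ranked variants per fold.
#' @param percentile Control-score percentile for the threshold
#'   (default 95).
#' @param denominator_mode Passed to the scoring step:
#'   `"per_individual"` (default) or `"fixed"`.
#' @param ranking_key `"or_descending"` (default) or `"abs_log_or"`.
#' @param refit_selection Re-rank and re-select variants inside every
#'   fold (default TRUE, the "from scratch" rule). FALSE freezes the
#'   selection computed on the full data and only refits the weights and
#'   threshold per fold.
#' @return A `loocv_config` list.
#' @export
loocv_config <- function(n_variants, percentile = 95,
                         denominator_mode = c("per_individual", "fixed"),
                         ranking_key = c("or_descending", "abs_log_or"),
                         refit_selection = TRUE) {
  stopifnot(n_variants >= 1, percentile > 0, percentile <= 100)
  structure(list(n_variants = as.integer(n_variants),
                 percentile = percentile,
                 denominator_mode = match.arg(denominator_mode),
                 ranking_key = match.arg(ranking_key),
                 refit_selection = isTRUE(refit_selection)),
            class = "loocv_config")
}

#' Remove one individual from per-variant allele counts
#'
#' Decrements the case or control allele counts by the individual's
#' contribution (minor alleles = dosage, major alleles = 2 - dosage at
#' non-missing variants). [update_counts_add()] is the exact inverse.
#'
#' @param counts Data frame from [variant_counts()].
#' @param genotypes Integer dosage vector for the individual (NA for
#'   missing calls), aligned with the rows of `counts`.
#' @param phenotype `"case"` or `"control"`.
#' @return The updated counts data frame.
#' @export
update_counts_remove <- function(counts, genotypes, phenotype) {
  stopifnot(length(genotypes) == nrow(counts),
            phenotype %in% c("case", "control"))
  obs <- !is.na(genotypes)
  g <- ifelse(obs, genotypes, 0L)
  dmin <- as.integer(g)
  dmaj <- as.integer(ifelse(obs, 2L - g, 0L))
  if (phenotype == "case") {
    counts$minor_case <- counts$minor_case - dmin
    counts$major_case <- counts$major_case - dmaj
    if (any(counts$minor_case < 0L) || any(counts$major_case < 0L)) {
      stop("count consistency error: case counts fell below zero")
    }
  } else {
    counts$minor_control <- counts$minor_control - dmin
    counts$major_control <- counts$major_control - dmaj
    if (any(counts$minor_control < 0L) || any(counts$major_control < 0L)) {
      stop("count consistency error: control counts fell below zero")
    }
  }
  counts
}

#' Add one individual back into per-variant allele counts
#'
#' Inverse of [update_counts_remove()].
#'
#' @inheritParams update_counts_remove
#' @return The updated counts data frame.
#' @export
update_counts_add <- function(counts, genotypes, phenotype) {
  stopifnot(length(genotypes) == nrow(counts),
            phenotype %in% c("case", "control"))
  obs <- !is.na(genotypes)
  g <- ifelse(obs, genotypes, 0L)
  dmin <- as.integer(g)
  dmaj <- as.integer(ifelse(obs, 2L - g, 0L))
  if (phenotype == "case") {
    counts$minor_case <- counts$minor_case + dmin
    counts$major_case <- counts$major_case + dmaj
  } else {
    counts$minor_control <- counts$minor_control + dmin
    counts$major_control <- counts$major_control + dmaj
  }
  counts
}

## score a genotype block (rows = individuals) with fold weights
.loo_score <- function(gblock, weights, denominator_mode) {
  obs <- !is.na(gblock)
  g0 <- gblock
  g0[!obs] <- 0L
  num <- as.numeric(g0 %*% weights)
  n_eff <- if (denominator_mode == "fixed") length(weights) else rowSums(obs)
  ifelse(rowSums(obs) == 0L, NA_real_, num / (2 * pmax(n_eff, 1L)))
}

#' Leave-one-out cross-validated predictions
#'
#' For each individual j: the per-variant allele counts exclude j;
#' variants are re-ranked by odds ratio and the top N re-selected (per
#' `config$refit_selection`); j's score is computed with the fold's log
#' odds ratios; the threshold is the configured percentile of the fold's
#' control scores (excluding j when j is a control, so the held-out
#' sample never informs its own rule); j is predicted a case when the
#' score strictly exceeds the threshold. The whole procedure is
#' deterministic.
#'
#' @param dataset A [genotype_dataset()] with at least 2 cases and 2
#'   controls among the phenotyped samples.
#' @param config A [loocv_config()].
#' @return A list with `predictions` (data frame: sample_id, sex,
#'   phenotype, threshold, score, prediction) and `table`
#'   (a `prediction_table` over all held-out predictions).
#' @export
loo_predict_all <- function(dataset, config) {
  stopifnot(inherits(config, "loocv_config"))
  validate_genotype_dataset(dataset)
  ph <- dataset$samples$phenotype
  use <- which(ph %in% c("case", "control"))
  if (sum(ph[use] == "case") < 2L || sum(ph[use] == "control") < 2L) {
    stop("loo_predict_all: need at least 2 cases and 2 controls")
  }
  g <- dataset$genotypes[use, , drop = FALSE]
  ph <- ph[use]
  counts_full <- variant_counts(subset_samples(dataset, use))
  n_sel <- min(config$n_variants, ncol(g))
  ctrl_rows <- which(ph == "control")

  fixed_sel <- NULL
  if (!config$refit_selection) {
    or_full <- allelic_odds_ratio(counts_full$minor_case, counts_full$major_case,
                                  counts_full$minor_control, counts_full$major_control)
    key <- if (config$ranking_key == "abs_log_or") abs(or_full$log_or) else or_full$odds_ratio
    fixed_sel <- order(-key, seq_along(key))[seq_len(n_sel)]
  }

  K <- length(use)
  score_j <- thr_j <- numeric(K)
  pred_j <- character(K)
  for (j in seq_len(K)) {
    cj <- update_counts_remove(counts_full, g[j, ], ph[j])
    or <- tryCatch(
      allelic_odds_ratio(cj$minor_case, cj$major_case,
                         cj$minor_control, cj$major_control),
      error = function(e) {
        stop("fold for sample ", dataset$samples$sample_id[use[j]], ": ",
             conditionMessage(e), call. = FALSE)
      })
    sel <- if (config$refit_selection) {
      key <- if (config$ranking_key == "abs_log_or") abs(or$log_or) else or$odds_ratio
      order(-key, seq_along(key))[seq_len(n_sel)]
    } else {
      fixed_sel
    }
    w <- or$log_or[sel]
    # threshold from the fold's controls (never including j)
    fold_ctrl <- setdiff(ctrl_rows, j)
    ctrl_scores <- .loo_score(g[fold_ctrl, sel, drop = FALSE], w,
                              config$denominator_mode)
    ctrl_scores <- ctrl_scores[!is.na(ctrl_scores)]
    if (length(ctrl_scores) == 0L) {
      stop("fold for sample ", dataset$samples$sample_id[use[j]],
           " has no scorable controls")
    }
    thr <- unname(stats::quantile(ctrl_scores, config$percentile / 100, type = 7))
    s <- .loo_score(g[j, sel, drop = FALSE], w, config$denominator_mode)
    score_j[j] <- s
    thr_j[j] <- thr
    pred_j[j] <- if (is.na(s)) NA_character_ else if (s > thr) "case" else "control"
  }

  predictions <- data.frame(
    sample_id = dataset$samples$sample_id[use],
    sex = dataset$samples$sex[use],
    phenotype = ph,
    threshold = thr_j,
    score = score_j,
    prediction = pred_j,
    stringsAsFactors = FALSE
  )
  list(predictions = predictions,
       table = prediction_table(predictions$prediction, predictions$phenotype))
}

#' Write LOO predictions as TSV
#'
#' @param loo Output of [loo_predict_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loo_predictions <- function(loo, path) {
  utils::write.table(loo$predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
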