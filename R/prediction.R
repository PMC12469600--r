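## Percentile-threshold classification, the 2x2 decision table and its
## metrics, the variant-count grid sweep, ROC smoothing and AUC.

#' Percentile threshold of control scores
#'
#' The classification threshold is a percentile (default the 95th) of
#' the control score distribution, computed by linear interpolation
#' between order statistics (R quantile type 7); `type = "nearest_rank"`
#' uses the nearest-rank convention (quantile type 1) instead.
#'
#' @param scores Numeric scores for all samples, named by sample id, or a
#'   `score_profile` data frame.
#' @param control_ids Ids (or logical/integer index) of control samples.
#' @param percentile Percentile in (0, 100] (default 95).
#' @param type `"linear"` (default) or `"nearest_rank"`.
#' @return The threshold, a single number.
#' @export
control_threshold <- function(scores, control_ids = NULL, percentile = 95,
                              type = c("linear", "nearest_rank")) {
  type <- match.arg(type)
  if (inherits(scores, "score_profile") || is.data.frame(scores)) {
    if (is.null(control_ids)) control_ids <- scores$phenotype == "control"
    s <- scores$score
    names(s) <- scores$sample_id
    scores <- s
  }
  ctrl <- if (is.character(control_ids)) scores[control_ids] else scores[control_ids]
  ctrl <- ctrl[!is.na(ctrl)]
  if (length(ctrl) == 0L) stop("control_threshold: no control scores")
  qt <- if (type == "linear") 7 else 1
  unname(stats::quantile(ctrl, probs = percentile / 100, type = qt))
}

#' Classify scores against a threshold
#'
#' An individual is predicted to be a case when their score strictly
#' exceeds the threshold ("exceeds" means ties go to control); a missing
#' score yields a missing prediction.
#'
#' @param scores Numeric vector (or `score_profile`).
#' @param threshold Finite numeric threshold.
#' @return Character vector of `"case"` / `"control"` / `NA`.
#' @export
classify <- function(scores, threshold) {
  if (!is.finite(threshold)) stop("classify: threshold must be finite")
  if (inherits(scores, "score_profile") || is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$sample_id)
  }
  out <- ifelse(is.na(scores), NA_character_,
                ifelse(scores > threshold, "case", "control"))
  out
}

#' Build the 2x2 decision table and its metrics
#'
#' Cross-tabulates predictions against known phenotypes:
#' a = cases predicted case, b = cases predicted control, c = controls
#' predicted case, d = controls predicted control. Derived metrics:
#' PPV = a/(a+c), NPV = d/(b+d), ACC = (a+d)/(a+b+c+d) (the proportion
#' of correct predictions), OR = ad/(bc), TPR = a/(a+b), FPR = c/(c+d),
#' misclassified = b+c. Metrics whose denominator is zero are `NA` with
#' `or_infinite` flagging the b*c == 0 < a*d case. Samples with missing
#' prediction or phenotype are excluded and counted in `n_excluded`.
#'
#' @param predictions Character vector of `"case"`/`"control"`/`NA`.
#' @param truth Character vector of known phenotypes, aligned with
#'   `predictions`.
#' @return A `prediction_table` (list).
#' @export
prediction_table <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  ok <- !is.na(predictions) & truth %in% c("case", "control")
  n_excluded <- sum(!ok)
  p <- predictions[ok]
  t_ <- truth[ok]
  a <- sum(t_ == "case" & p == "case")
  b <- sum(t_ == "case" & p == "control")
  c_ <- sum(t_ == "control" & p == "case")
  d <- sum(t_ == "control" & p == "control")
  prediction_table_from_counts(a, b, c_, d, n_excluded)
}

#' Decision-table metrics from the four counts
#'
#' @param a,b,c_,d The table counts (see [prediction_table()]).
#' @param n_excluded Number of samples excluded before tabulation.
#' @return A `prediction_table` (list).
#' @export
prediction_table_from_counts <- function(a, b, c_, d, n_excluded = 0L) {
  total <- a + b + c_ + d
  div <- function(num, den) if (den > 0) num / den else NA_real_
  or_infinite <- (b * c_ == 0) && (a * d > 0)
  structure(list(
    a = a, b = b, c = c_, d = d,
    ppv = div(a, a + c_),
    npv = div(d, b + d),
    acc = div(a + d, total),
    tpr = div(a, a + b),
    fpr = div(c_, c_ + d),
    odds_ratio = if (or_infinite) Inf else if (b * c_ > 0) (a * d) / (b * c_) else NA_real_,
    or_infinite = or_infinite,
    misclassified = b + c_,
    misclassification_rate = div(b + c_, total),
    n_excluded = n_excluded
  ), class = "prediction_table")
}

#' @export
print.prediction_table <- function(x, ...) {
  cat("decision table (rows = known phenotype)\n")
  cat(sprintf("           pred case  pred control\n"))
  cat(sprintf("  case     %9d  %12d\n", x$a, x$b))
  cat(sprintf("  control  %9d  %12d\n", x$c, x$d))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat("  PPV ", fmt(x$ppv), "  NPV ", fmt(x$npv), "  ACC ", fmt(x$acc), "\n", sep = "")
  ortxt <- if (x$or_infinite) "Inf" else fmt(x$odds_ratio)
  cat("  OR ", ortxt, "  misclassified ", x$misclassified,
      " (", fmt(x$misclassification_rate), ")\n", sep = "")
  invisible(x)
}

#' Sweep the variant-count grid
#'
#' For each N in `grid`: select the top-N ranked variants, compute the
#' polygenic score for every sample, set the threshold at `percentile`
#' of the control scores, classify, and tabulate. Values of N exceeding
#' the available ranking are clipped with a warning.
#'
#' @param dataset A [genotype_dataset()].
#' @param ranked_stats Output of [rank_variants()] (already sorted).
#' @param grid Integer vector of variant counts N (default the package
#'   grid, see [default_variant_grid()]).
#' @param percentile Control-score percentile for the threshold.
#' @param denominator_mode Passed to [compute_prs()].
#' @return A `roc_series`: list with `grid`, `tpr`, `fpr`, `tables`
#'   (one `prediction_table` per N); smoothing fields are filled by
#'   [smooth_roc()].
#' @export
sweep_grid <- function(dataset, ranked_stats, grid = default_variant_grid(),
                       percentile = 95,
                       denominator_mode = "per_individual") {
  avail <- nrow(ranked_stats)
  if (any(grid > avail)) {
    warning("grid values above ", avail, " available variants were clipped")
    grid <- pmin(grid, avail)
  }
  grid <- sort(unique(as.integer(grid)))
  tables <- vector("list", length(grid))
  tpr <- fpr <- numeric(length(grid))
  for (k in seq_along(grid)) {
    sel <- ranked_stats[seq_len(grid[k]), , drop = FALSE]
    prof <- compute_prs(dataset, sel, denominator_mode = denominator_mode)
    thr <- control_threshold(prof, percentile = percentile)
    pred <- classify(prof, thr)
    tab <- prediction_table(pred, prof$phenotype)
    tables[[k]] <- tab
    tpr[k] <- tab$tpr
    fpr[k] <- tab$fpr
  }
  structure(list(grid = grid, tpr = tpr, fpr = fpr,
                 smoothed_tpr = NULL, smoothed_fpr = NULL, auc = NULL,
                 tables = tables),
            class = "roc_series")
}

#' The default variant-count grid
#'
#' The sequence 5, 10, 20, 50, 100, 200, 500, 1000, 2000, 5000, 10000,
#' 20000, 50000 used for accuracy-vs-N sweeps.
#'
#' @return Integer vector.
#' @export
default_variant_grid <- function() {
  c(5L, 10L, 20L, 50L, 100L, 200L, 500L, 1000L, 2000L, 5000L, 10000L,
    20000L, 50000L)
}

## one pass of the overlapping 3-point moving average; endpoints fixed
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out
}

## ROC validity: TPR >= FPR elementwise and TPR non-decreasing along the
## FPR-sorted traversal used for AUC
roc_conforms <- function(tpr, fpr, tol = 1e-9) {
  if (any(tpr < fpr - tol)) return(FALSE)
  ord <- order(fpr, seq_along(fpr))
  all(diff(tpr[ord]) >= -tol)
}

#' Smooth a ragged ROC series
#'
#' Raw (TPR, FPR) series from a variant-count sweep are generally ragged.
#' Both sequences are repeatedly replaced by overlapping 3-point moving
#' averages (endpoints held fixed) until the curve is a proper ROC:
#' TPR >= FPR everywhere and TPR non-decreasing along increasing FPR.
#' A series already conforming is returned unchanged.
#'
#' @param series A `roc_series` from [sweep_grid()], or a list with
#'   `tpr` and `fpr`.
#' @param max_iter Iteration cap (default 1000); exceeded means a
#'   convergence error carrying diagnostics.
#' @return The series with `smoothed_tpr`, `smoothed_fpr`, `auc` filled
#'   and attribute `iterations`.
#' @export
smooth_roc <- function(series, max_iter = 1000) {
  tpr <- series$tpr
  fpr <- series$fpr
  if (length(tpr) == 0L) stop("smooth_roc: empty series")
  it <- 0L
  while (!roc_conforms(tpr, fpr)) {
    if (it >= max_iter) {
      stop("smooth_roc: conditions not met after ", max_iter,
           " iterations (max TPR deficit ",
           signif(max(series$fpr - series$tpr), 3), ")")
    }
    tpr <- smooth3(tpr)
    fpr <- smooth3(fpr)
    it <- it + 1L
  }
  series$smoothed_tpr <- tpr
  series$smoothed_fpr <- fpr
  series$auc <- compute_auc(list(tpr = tpr, fpr = fpr))
  attr(series, "iterations") <- it
  series
}

#' Area under an ROC curve by trapezoidal integration
#'
#' Points are sorted by FPR (duplicated FPR values have their TPRs
#' averaged), the endpoints (0, 0) and (1, 1) are appended, and the area
#' is accumulated by the trapezoid rule.
#'
#' @param series A list with `tpr` and `fpr` (smoothed values are used
#'   when present).
#' @return AUC in 0..1.
#' @export
compute_auc <- function(series) {
  tpr <- if (!is.null(series$smoothed_tpr)) series$smoothed_tpr else series$tpr
  fpr <- if (!is.null(series$smoothed_fpr)) series$smoothed_fpr else series$fpr
  keep <- !is.na(tpr) & !is.na(fpr)
  tpr <- tpr[keep]
  fpr <- fpr[keep]
  if (length(tpr) == 0L) stop("compute_auc: no points")
  agg <- tapply(tpr, fpr, mean)
  # appended corners may duplicate an existing abscissa; the resulting
  # vertical segment has zero width and contributes nothing
  x <- c(0, as.numeric(names(agg)), 1)
  y <- c(0, as.numeric(agg), 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc_series <- function(x, ...) {
  cat("roc_series over", length(x$grid), "variant counts\n")
  df <- data.frame(N = x$grid, TPR = round(x$tpr, 4), FPR = round(x$fpr, 4))
  if (!is.null(x$smoothed_tpr)) {
    df$sTPR <- round(x$smoothed_tpr, 4)
    df$sFPR <- round(x$smoothed_fpr, 4)
  }
  print(df, row.names = FALSE)
  if (!is.null(x$auc)) cat("AUC:", round(x$auc, 4), "\n")
  invisible(x)
}

#' Write per-N sweep results as TSV
#'
#' One row per grid value with the decision-table counts and metrics
#' (N, a, b, c, d, PPV, NPV, OR, ACC, misclassified, rate).
#'
#' @param series A `roc_series` with `tables`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(series, path) {
  rows <- lapply(seq_along(series$grid), function(k) {
    t_ <- series$tables[[k]]
    data.frame(N = series$grid[k], a = t_$a, b = t_$b, c = t_$c, d = t_$d,
               ppv = t_$ppv, npv = t_$npv, odds_ratio = t_$odds_ratio,
               acc = t_$acc, misclassified = t_$misclassified,
               misclassification_rate = t_$misclassification_rate)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an ROC series as TSV
#'
#' @param series A `roc_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc_series <- function(series, path) {
  df <- data.frame(N = series$grid, tpr = series$tpr, fpr = series$fpr)
  if (!is.null(series$smoothed_tpr)) {
    df$smoothed_tpr <- series$smoothed_tpr
    df$smoothed_fpr <- series$smoothed_fpr
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
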