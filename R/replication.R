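## Replication by list overlap: is the number of variants shared between
## the top-k lists of two independent datasets larger than expected for
## two uniform-random subsets of the same universe? The Monte-Carlo null
## literally re-draws the two subsets; an exact hypergeometric tail
## serves as the analytic oracle (the overlap of two uniform random
## subsets of sizes k1 and k2 from m items is hypergeometric with
## population m, k1 successes and k2 draws).

#' Number of identifiers shared by two lists
#'
#' @param list1,list2 Vectors of unique identifiers.
#' @return The intersection size.
#' @export
overlap_count <- function(list1, list2) {
  if (anyDuplicated(list1)) stop("duplicates in list1")
  if (anyDuplicated(list2)) stop("duplicates in list2")
  length(intersect(list1, list2))
}

#' Monte-Carlo overlap replication test
#'
#' Each replicate draws two independent uniform-random subsets without
#' replacement (sizes `k1` and `k2`) from a universe of `m_universe`
#' items and records their overlap. The empirical significance level is
#' the add-one proportion of replicates whose overlap reaches the
#' observed count: (number of replicates with overlap >= observed + 1) /
#' (n_reps + 1), so it is never zero. `method = "hypergeometric"` draws
#' the overlap directly from its exact null distribution instead of
#' materializing the subsets; the two samplers target the same
#' distribution.
#'
#' @param m_universe Size of the shared variant universe.
#' @param k1,k2 Sizes of the two top lists.
#' @param observed_shared Observed overlap.
#' @param n_reps Number of Monte-Carlo replicates (default 100000).
#' @param seed Integer seed; required.
#' @param method `"subsets"` (default, literal subset resampling) or
#'   `"hypergeometric"` (fast path).
#' @return An `overlap_test_result` list: `m_universe`, `k1`, `k2`,
#'   `observed_shared`, `n_reps`, `empirical_p`, `null_median`,
#'   `null_mean`, `exact_mean`, `seed`, `method`.
#' @export
replic2 <- function(m_universe, k1, k2, observed_shared, n_reps = 100000,
                    seed, method = c("subsets", "hypergeometric")) {
  method <- match.arg(method)
  if (missing(seed)) stop("replic2: seed is required")
  if (k1 > m_universe || k2 > m_universe) stop("subset size exceeds universe")
  if (observed_shared > min(k1, k2)) stop("observed overlap exceeds min(k1, k2)")
  if (observed_shared < 0 || n_reps < 1) stop("invalid arguments")
  set.seed(seed)
  if (method == "hypergeometric") {
    ov <- stats::rhyper(n_reps, k1, m_universe - k1, k2)
  } else {
    ov <- integer(n_reps)
    marks <- logical(m_universe)
    for (r in seq_len(n_reps)) {
      s1 <- sample.int(m_universe, k1)
      s2 <- sample.int(m_universe, k2)
      marks[s1] <- TRUE
      ov[r] <- sum(marks[s2])
      marks[s1] <- FALSE
    }
  }
  structure(list(
    m_universe = m_universe, k1 = k1, k2 = k2,
    observed_shared = observed_shared, n_reps = n_reps,
    empirical_p = (sum(ov >= observed_shared) + 1) / (n_reps + 1),
    null_median = stats::median(ov),
    null_mean = mean(ov),
    exact_mean = k1 * k2 / m_universe,
    seed = seed, method = method
  ), class = "overlap_test_result")
}

#' @export
print.overlap_test_result <- function(x, ...) {
  cat("overlap replication test\n")
  cat("  universe ", x$m_universe, ", list sizes ", x$k1, " and ", x$k2, "\n", sep = "")
  cat("  observed shared: ", x$observed_shared, "\n", sep = "")
  cat("  null median ", x$null_median, ", null mean ", round(x$null_mean, 2),
      " (exact mean ", round(x$exact_mean, 2), ")\n", sep = "")
  cat("  empirical p ", format(x$empirical_p, digits = 4), " (", x$n_reps,
      " replicates, seed ", x$seed, ", method ", x$method, ")\n", sep = "")
  invisible(x)
}

#' Exact hypergeometric tail for the overlap null
#'
#' P(X >= observed) where X ~ hypergeometric(m, k1, k2): the exact null
#' distribution of the overlap of two independent uniform-random subsets.
#'
#' @inheritParams replic2
#' @return A list with `p_value` (upper tail including the observed
#'   count) and `mean` (k1 * k2 / m).
#' @export
hypergeom_overlap_pvalue <- function(m_universe, k1, k2, observed_shared) {
  if (k1 > m_universe || k2 > m_universe) stop("subset size exceeds universe")
  if (observed_shared > min(k1, k2)) stop("observed overlap exceeds min(k1, k2)")
  p <- stats::phyper(observed_shared - 1, k1, m_universe - k1, k2,
                     lower.tail = FALSE)
  list(p_value = p, mean = k1 * k2 / m_universe)
}

#' Variants shared by the tops of two rankings
#'
#' Intersects the top-k variant lists of two ranked datasets (for
#' example, males and females) and keeps the variants whose odds ratio
#' is at least `min_or` in BOTH datasets. Output rows are sorted by
#' (chromosome, bp) when positional metadata is supplied.
#'
#' @param ranked_a,ranked_b Outputs of [rank_variants()] over the same
#'   variant universe.
#' @param k Top-list size.
#' @param min_or Minimum odds ratio required in both datasets
#'   (default 1.0, i.e. no filter beyond list membership).
#' @param variants Optional variant metadata data frame (`variant_id`,
#'   `chromosome`, `bp`) used for sorting the report.
#' @return Data frame: `variant_id`, `chromosome`, `bp`, `or_a`, `or_b`.
#' @export
shared_top_variants <- function(ranked_a, ranked_b, k, min_or = 1.0,
                                variants = NULL) {
  if (!setequal(ranked_a$variant_id, ranked_b$variant_id)) {
    nd <- length(union(setdiff(ranked_a$variant_id, ranked_b$variant_id),
                       setdiff(ranked_b$variant_id, ranked_a$variant_id)))
    stop("rankings cover different universes (symmetric difference: ", nd,
         " variants)")
  }
  top_a <- utils::head(ranked_a$variant_id, k)
  top_b <- utils::head(ranked_b$variant_id, k)
  shared <- intersect(top_a, top_b)
  or_a <- ranked_a$odds_ratio[match(shared, ranked_a$variant_id)]
  or_b <- ranked_b$odds_ratio[match(shared, ranked_b$variant_id)]
  keep <- or_a >= min_or & or_b >= min_or
  out <- data.frame(variant_id = shared[keep], or_a = or_a[keep],
                    or_b = or_b[keep], stringsAsFactors = FALSE)
  if (!is.null(variants)) {
    i <- match(out$variant_id, variants$variant_id)
    out$chromosome <- variants$chromosome[i]
    out$bp <- variants$bp[i]
    out <- out[order(suppressWarnings(as.numeric(out$chromosome)),
                     out$chromosome, out$bp), ]
    out <- out[, c("variant_id", "chromosome", "bp", "or_a", "or_b")]
    rownames(out) <- NULL
  }
  out
}
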