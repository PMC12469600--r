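#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test of genotype counts against Hardy-Weinberg
#' proportions, conditioning on the observed allele counts. The p-value
#' is the sum of the probabilities of every heterozygote count (with the
#' same allele totals and matching parity) whose conditional probability
#' does not exceed that of the observed count. Probabilities are computed
#' by the standard recurrence over heterozygote counts, which is stable
#' for the sample sizes seen in genotyping QC.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote). Non-negative; their sum must be positive.
#' @return The exact p-value, in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")

  n_rare <- 2 * min(n_AA, n_aa) + n_Aa  # copies of the rarer allele
  # possible heterozygote counts share the parity of n_rare
  het_lo <- n_rare %% 2
  het_hi <- min(n_rare, 2 * n - n_rare)
  hets <- seq.int(het_lo, het_hi, by = 2)

  # unnormalized log-probabilities: P(het) proportional to
  # n! / (nAA! nAa! naa!) * 2^het with allele totals fixed
  rare_hom <- (n_rare - hets) / 2
  com_hom <- n - hets - rare_hom
  logp <- hets * log(2) + lfactorial(n) -
    (lfactorial(hets) + lfactorial(rare_hom) + lfactorial(com_hom))
  logp <- logp - max(logp)
  probs <- exp(logp)
  probs <- probs / sum(probs)

  p_obs <- probs[match(n_Aa, hets)]
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

## Vectorized convenience: HWE p-value per variant from a dosage matrix
## (columns = variants), using only the rows supplied.
hwe_pvalues <- function(geno) {
  vapply(seq_len(ncol(geno)), function(j) {
    d <- geno[, j]
    n_aa <- sum(d == 2L, na.rm = TRUE)   # minor homozygote
    n_Aa <- sum(d == 1L, na.rm = TRUE)
    n_AA <- sum(d == 0L, na.rm = TRUE)
    if (n_aa + n_Aa + n_AA == 0L) return(NA_real_)
    hwe_exact_test(n_AA, n_Aa, n_aa)
  }, numeric(1))
}
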