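# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no stored data.

# quick dataset constructor with synthesized metadata
make_ds <- function(geno, phenotype, sex = NULL, chromosome = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  m <- ncol(geno)
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
  if (is.null(chromosome)) chromosome <- rep("1", m)
  genotype_dataset(
    geno,
    data.frame(sample_id = sprintf("s%03d", seq_len(n)), sex = sex,
               phenotype = phenotype, stringsAsFactors = FALSE),
    data.frame(variant_id = sprintf("v%03d", seq_len(m)),
               chromosome = chromosome, bp = seq_len(m) * 100L,
               allele_minor = "A", allele_major = "B",
               stringsAsFactors = FALSE)
  )
}

# random valid dataset, minor-oriented so PLINK round trips are exact
random_ds <- function(n, m, seed, miss = 0.05, maf_hi = 0.5) {
  set.seed(seed)
  maf <- runif(m, 0.05, maf_hi)
  g <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  if (miss > 0) g[runif(n * m) < miss] <- NA_integer_
  ph <- sample(c("case", "control"), n, replace = TRUE)
  sx <- sample(c("male", "female", "unknown"), n, replace = TRUE,
               prob = c(0.45, 0.45, 0.1))
  recompute_minor_allele(make_ds(g, ph, sex = sx))
}

# --- independent oracles -------------------------------------------------

# HWE exact test by direct enumeration with choose()-based probabilities
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  hets <- seq.int(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- vapply(hets, function(h) {
    r <- (n_rare - h) / 2
    choose(n, h) * choose(n - h, r) * 2^h
  }, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# leave-one-out by literally deleting each row and rerunning the full
# ranking/selection/scoring/threshold pipeline
loo_oracle <- function(ds, n_var, percentile = 95, refit = TRUE) {
  ph <- ds$samples$phenotype
  use <- which(ph %in% c("case", "control"))
  fixed_sel <- NULL
  if (!refit) {
    rk <- rank_variants(subset_samples(ds, use))
    fixed_sel <- head(rk$variant_id, n_var)
  }
  out <- data.frame(sample_id = ds$samples$sample_id[use],
                    score = NA_real_, threshold = NA_real_,
                    prediction = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(use)) {
    j <- use[i]
    fold <- subset_samples(ds, setdiff(use, j))
    rk <- rank_variants(fold)
    sel <- if (refit) head(rk, n_var) else rk[match(fixed_sel, rk$variant_id), ]
    ctrl_prof <- compute_prs(fold, sel)
    thr <- control_threshold(ctrl_prof, percentile = percentile)
    s <- compute_prs(subset_samples(ds, j), sel)$score
    out$score[i] <- s
    out$threshold[i] <- thr
    out$prediction[i] <- if (is.na(s)) NA_character_ else
      if (s > thr) "case" else "control"
  }
  out
}

# enumerate the exact overlap distribution of two random k-subsets of m
overlap_enum_pvalue <- function(m, k1, k2, observed) {
  subs <- utils::combn(m, k2, simplify = FALSE)
  ref <- seq_len(k1)  # by symmetry, condition on the first subset
  hits <- vapply(subs, function(s) length(intersect(s, ref)), numeric(1))
  mean(hits >= observed)
}
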