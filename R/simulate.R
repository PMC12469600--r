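## Synthetic case-control cohorts with sex-specific planted allelic
## effects. Variants are biallelic, in linkage equilibrium, with
## genotypes drawn under Hardy-Weinberg proportions; disease liability is
## log-additive in the planted per-allele effects (so the planted beta is
## the log of the allelic odds ratio the scoring module estimates); the
## logistic intercept is solved by bisection so the expected case
## fraction matches the target prevalence.

#' Simulation configuration
#'
#' Defaults mirror the cohort shape of a sex-stratified schizophrenia
#' case-control study (2164 males, 932 females, case fraction 0.337)
#' at a desk-scale variant count.
#'
#' @param n_male,n_female Sample counts per sex.
#' @param n_variants Total variant count.
#' @param maf_range Minor-allele-frequency range (uniform draw).
#' @param n_effect_male,n_effect_female Counts of causal variants
#'   specific to each sex.
#' @param n_effect_shared Causal variants shared by both sexes (same
#'   effect size in both).
#' @param effect_log_or_range Range of planted per-allele log odds
#'   ratios (uniform draw).
#' @param prevalence_target Target case fraction.
#' @param missing_rate Probability that any genotype call is missing.
#' @param case_control_ratio Optional target case fraction after
#'   downsampling the over-represented phenotype; `NULL` (default)
#'   keeps all samples.
#' @param seed Integer seed; required for reproducibility.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_male = 2164, n_female = 932, n_variants = 2000,
                       maf_range = c(0.01, 0.5),
                       n_effect_male = 50, n_effect_female = 50,
                       n_effect_shared = 20,
                       effect_log_or_range = c(0.2, 0.7),
                       prevalence_target = 0.337, missing_rate = 0.002,
                       case_control_ratio = NULL, seed = 1) {
  cfg <- list(n_male = as.integer(n_male), n_female = as.integer(n_female),
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              n_effect_male = as.integer(n_effect_male),
              n_effect_female = as.integer(n_effect_female),
              n_effect_shared = as.integer(n_effect_shared),
              effect_log_or_range = as.numeric(effect_log_or_range),
              prevalence_target = as.numeric(prevalence_target),
              missing_rate = as.numeric(missing_rate),
              case_control_ratio = case_control_ratio,
              seed = as.integer(seed))
  n_eff <- cfg$n_effect_male + cfg$n_effect_female + cfg$n_effect_shared
  stopifnot(n_eff <= cfg$n_variants,
            cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$effect_log_or_range[1] <= cfg$effect_log_or_range[2],
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$prevalence_target > 0, cfg$prevalence_target < 1)
  structure(cfg, class = "sim_config")
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_sim_config`, a [sim_config()]; for
#'   `write_sim_config`, `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate a case-control cohort with sex-specific effects
#'
#' Genotypes: per-variant MAF drawn uniformly from `maf_range`, dosages
#' binomial(2, MAF) (Hardy-Weinberg), variants in linkage equilibrium.
#' The first `n_effect_shared` variants are causal in both sexes, the
#' next `n_effect_male` in males only, then `n_effect_female` in females
#' only; each causal variant gets a log odds ratio drawn uniformly from
#' `effect_log_or_range`. Phenotype is Bernoulli(logistic(intercept +
#' sum of beta * dosage over the sex's causal set)), with the intercept
#' solved by bisection so the expected case fraction equals
#' `prevalence_target` (tolerance 5e-3). Missing calls are planted
#' uniformly at `missing_rate` after phenotype assignment. Causal ids
#' and betas are recorded in attributes `causal` (data frame) for
#' parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return A [genotype_dataset()] with attribute `causal`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_male + config$n_female
  m <- config$n_variants
  sex <- c(rep("male", config$n_male), rep("female", config$n_female))

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  g <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)

  n_sh <- config$n_effect_shared
  n_ma <- config$n_effect_male
  n_fe <- config$n_effect_female
  idx_shared <- seq_len(n_sh)
  idx_male <- seq_len(n_ma) + n_sh
  idx_female <- seq_len(n_fe) + n_sh + n_ma
  causal_idx <- c(idx_shared, idx_male, idx_female)
  beta <- stats::runif(length(causal_idx), config$effect_log_or_range[1],
                       config$effect_log_or_range[2])

  eta <- numeric(n)
  male_set <- c(idx_shared, idx_male)
  female_set <- c(idx_shared, idx_female)
  bmap <- stats::setNames(beta, causal_idx)
  if (length(male_set)) {
    eta[sex == "male"] <- g[sex == "male", male_set, drop = FALSE] %*%
      bmap[as.character(male_set)]
  }
  if (length(female_set)) {
    eta[sex == "female"] <- g[sex == "female", female_set, drop = FALSE] %*%
      bmap[as.character(female_set)]
  }

  # bisection on the expected case fraction
  target <- config$prevalence_target
  f <- function(c0) mean(stats::plogis(eta + c0)) - target
  lo <- -30 - max(eta); hi <- 30 - min(eta)
  if (f(lo) > 0 || f(hi) < 0) stop("prevalence target unattainable")
  intercept <- NA_real_
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (abs(f(mid)) < 5e-4) {
      intercept <- mid
      break
    }
  }
  if (is.na(intercept)) intercept <- (lo + hi) / 2
  if (abs(f(intercept)) > 5e-3) stop("prevalence bisection did not converge")

  phen <- ifelse(stats::runif(n) < stats::plogis(eta + intercept),
                 "case", "control")

  keep <- seq_len(n)
  if (!is.null(config$case_control_ratio)) {
    r <- config$case_control_ratio
    ncase <- sum(phen == "case")
    nctrl <- sum(phen == "control")
    # downsample whichever group is over-represented relative to r
    if (ncase / (ncase + nctrl) > r) {
      want_case <- floor(r / (1 - r) * nctrl)
      drop <- sample(which(phen == "case"), ncase - want_case)
    } else {
      want_ctrl <- floor((1 - r) / r * ncase)
      drop <- sample(which(phen == "control"), nctrl - want_ctrl)
    }
    keep <- setdiff(keep, drop)
  }

  g <- g[keep, , drop = FALSE]
  sex <- sex[keep]
  phen <- phen[keep]
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(g)) < config$missing_rate
    g[miss] <- NA_integer_
  }

  samples <- data.frame(
    sample_id = sprintf("S%05d", keep),
    sex = sex, phenotype = phen, stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = sprintf("var%06d", seq_len(m)),
    chromosome = "1", bp = seq_len(m) * 1000L,
    allele_minor = "A", allele_major = "B", stringsAsFactors = FALSE)

  ds <- genotype_dataset(g, samples, variants)
  ds <- recompute_minor_allele(ds)
  attr(ds, "causal") <- data.frame(
    variant_id = variants$variant_id[causal_idx],
    beta = beta,
    stratum = c(rep("shared", n_sh), rep("male", n_ma), rep("female", n_fe)),
    stringsAsFactors = FALSE)
  attr(ds, "sim_config") <- config
  ds
}

#' Plant deterministic QC failures into a dataset
#'
#' Rewrites named variants so that each exhibits exactly one requested
#' failure mode, for exercising the QC filters:
#' \describe{
#'   \item{`callrate`}{sets the first 20\% of calls missing}
#'   \item{`monomorphic`}{sets all calls to dosage 0}
#'   \item{`hwe`}{common alleles with no heterozygotes (alternating
#'     dosages 0 and 2), a gross Hardy-Weinberg violation}
#'   \item{`low_maf`}{one heterozygote, all other calls 0 (MAF well
#'     below 0.01 for cohorts of 51+ samples)}
#'   \item{`duplicate`}{exact copy of the previous variant's dosages,
#'     for the LD pruner}
#' }
#'
#' @param dataset A [genotype_dataset()].
#' @param failures Data frame with columns `variant_id` and `mode`.
#' @return The modified dataset.
#' @export
plant_qc_failures <- function(dataset, failures) {
  g <- dataset$genotypes
  n <- nrow(g)
  for (i in seq_len(nrow(failures))) {
    j <- match(failures$variant_id[i], dataset$variants$variant_id)
    if (is.na(j)) stop("unknown variant id: ", failures$variant_id[i])
    mode <- failures$mode[i]
    if (mode == "callrate") {
      g[seq_len(ceiling(0.2 * n)), j] <- NA_integer_
    } else if (mode == "monomorphic") {
      g[, j] <- 0L
    } else if (mode == "hwe") {
      g[, j] <- rep_len(c(0L, 2L), n)
    } else if (mode == "low_maf") {
      g[, j] <- 0L
      g[1L, j] <- 1L
    } else if (mode == "duplicate") {
      if (j < 2L) stop("cannot duplicate: no previous variant")
      g[, j] <- g[, j - 1L]
    } else {
      stop("unknown failure mode: ", mode)
    }
  }
  dataset$genotypes <- g
  dataset
}
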