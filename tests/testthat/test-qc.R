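test_that("call-rate filter uses a strict inequality on the missing rate", {
  g <- matrix(0:1, 10, 3)
  g[1:2, 1] <- NA  # rate 0.2 -> removed
  g[1, 2] <- NA    # rate 0.1 -> retained ("exceeding" 0.10 is strict)
  d <- make_ds(g, rep(c("case", "control"), 5))
  res <- filter_callrate(d, 0.10)
  expect_identical(res$removed_ids, "v001")
  expect_identical(res$dataset$variants$variant_id, c("v002", "v003"))
})

test_that("call-rate removal set matches a brute-force recount", {
  d <- random_ds(20, 50, seed = 11, miss = 0.12)
  res <- filter_callrate(d, 0.10)
  oracle <- d$variants$variant_id[
    sapply(seq_len(50), function(j) sum(is.na(d$genotypes[, j])) / 20 > 0.10)]
  expect_setequal(res$removed_ids, oracle)
})

test_that("monomorphic filter removes constant and all-missing variants", {
  g <- cbind(rep(0L, 6), rep(2L, 6), c(0L, 0L, 1L, 0L, 0L, 0L),
             rep(NA_integer_, 6))
  d <- make_ds(g, rep(c("case", "control"), 3))
  res <- filter_monomorphic(d)
  expect_setequal(res$removed_ids, c("v001", "v002", "v004"))
  expect_identical(res$dataset$variants$variant_id, "v003")
})

test_that("HWE exact test matches hand-checkable cases", {
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  expect_equal(hwe_exact_test(3, 4, 3), hwe_enum_oracle(3, 4, 3),
               tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("HWE exact test equals enumeration for a sweep of small totals", {
  # full sweep to total 30 runs in the acceptance suite; spot-check here
  for (n in c(5L, 9L, 16L)) {
    for (n_AA in 0:n) for (n_Aa in 0:(n - n_AA)) {
      n_aa <- n - n_AA - n_Aa
      expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
                   hwe_enum_oracle(n_AA, n_Aa, n_aa), tolerance = 1e-12)
    }
  }
})

test_that("HWE filter tests controls only and respects alpha", {
  # variant 1: perfect HWE in 100 controls, gross violation in cases
  ctrl_ok <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  case_bad <- rep_len(c(0L, 2L), 60)
  # variant 2: het-free common variant in controls -> removed
  ctrl_bad <- rep_len(c(0L, 2L), 100)
  g <- cbind(c(case_bad, ctrl_ok), c(rep_len(c(0L, 1L, 2L, 1L), 60), ctrl_bad))
  d <- make_ds(g, c(rep("case", 60), rep("control", 100)))
  res <- filter_hwe(d, alpha = 1e-3)
  expect_identical(res$removed_ids, "v002")

  expect_identical(filter_hwe(d, alpha = 0)$removed_ids, character(0))
  no_ctrl <- make_ds(g, rep("case", 160))
  expect_error(filter_hwe(no_ctrl), "no controls")
})

test_that("MAF filter boundary is strict and matches brute-force counting", {
  # 50 samples: 1 minor allele -> MAF 0.01 retained; needs < 1 to go
  g <- cbind(c(1L, rep(0L, 49)), rep(0L, 50), rep(1L, 50))
  g[1, 2] <- 1L  # MAF 0.01
  d0 <- make_ds(cbind(c(1L, rep(0L, 99))), rep(c("case", "control"), 50))
  expect_identical(filter_maf(d0, 0.01)$removed_ids, "v001")  # MAF 0.005

  d <- make_ds(g, rep(c("case", "control"), 25))
  expect_identical(filter_maf(d, 0.01)$removed_ids, character(0))

  dr <- random_ds(30, 40, seed = 13, miss = 0.1, maf_hi = 0.2)
  res <- filter_maf(dr, 0.05)
  oracle <- dr$variants$variant_id[sapply(seq_len(40), function(j) {
    x <- dr$genotypes[, j]
    f <- sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
    min(f, 1 - f) < 0.05
  })]
  expect_setequal(res$removed_ids, oracle)
})

test_that("VIF pruning keeps independent variants and drops exact duplicates", {
  set.seed(21)
  g <- matrix(rbinom(200 * 12, 2, 0.3), 200, 12)
  d <- make_ds(g, rep(c("case", "control"), 100))
  expect_length(ld_prune_vif(d, window = 12, step = 3)$removed_ids, 0)

  g2 <- g
  g2[, 7] <- g2[, 6]  # exact duplicate, VIF unbounded
  d2 <- make_ds(g2, rep(c("case", "control"), 100))
  res <- ld_prune_vif(d2, window = 12, step = 3)
  expect_identical(res$removed_ids, "v007")  # tie removes the larger index
})

test_that("VIF pruning matches a direct least-squares oracle", {
  set.seed(22)
  n <- 300
  g <- matrix(rbinom(n * 10, 2, 0.4), n, 10)
  # plant a pair with r^2 about 0.9
  g[, 4] <- ifelse(runif(n) < 0.95, g[, 3], rbinom(n, 2, 0.4))
  d <- make_ds(g, rep(c("case", "control"), n / 2))
  res <- ld_prune_vif(d, window = 10, step = 10, vif_threshold = 2)

  # oracle: iteratively recompute every VIF with lm() and apply the rule
  keep <- 1:10
  repeat {
    vifs <- sapply(seq_along(keep), function(i) {
      y <- g[, keep[i]]
      r2 <- summary(lm(y ~ g[, keep[-i], drop = FALSE]))$r.squared
      1 / max(1 - r2, 1e-12)
    })
    if (max(vifs) <= 2) break
    keep <- keep[-max(which(vifs >= max(vifs) * (1 - 1e-9)))]
  }
  expect_setequal(res$removed_ids, sprintf("v%03d", setdiff(1:10, keep)))
})

test_that("VIF pruning is idempotent", {
  set.seed(23)
  n <- 150
  g <- matrix(rbinom(n * 30, 2, 0.35), n, 30)
  for (j in c(5, 12, 25)) g[, j] <- g[, j - 1]          # duplicates
  g[, 18] <- ifelse(runif(n) < 0.9, g[, 17], g[, 18])   # strong LD
  d <- make_ds(g, rep(c("case", "control"), n / 2))
  p1 <- ld_prune_vif(d, window = 8, step = 3)
  p2 <- ld_prune_vif(p1$dataset, window = 8, step = 3)
  expect_length(p2$removed_ids, 0)
  expect_error(ld_prune_vif(d, window = 1), "window")
})

test_that("windows never span chromosomes", {
  set.seed(24)
  g <- matrix(rbinom(100 * 4, 2, 0.4), 100, 4)
  g[, 3] <- g[, 2]  # duplicate pair straddling the chromosome boundary
  d <- make_ds(g, rep(c("case", "control"), 50),
               chromosome = c("1", "1", "2", "2"))
  res <- ld_prune_vif(d, window = 4, step = 1)
  expect_length(res$removed_ids, 0)
})

test_that("run_qc applies filters in order and attributes to the first", {
  d <- random_ds(400, 20, seed = 31, miss = 0, maf_hi = 0.45)
  fails <- data.frame(
    variant_id = c("v002", "v005", "v008", "v011", "v015"),
    mode = c("callrate", "monomorphic", "hwe", "low_maf", "duplicate"))
  d2 <- plant_qc_failures(d, fails)
  res <- run_qc(d2)
  rep_ <- res$report
  expect_equal(rep_$n_removed_callrate, 1)
  expect_equal(rep_$n_removed_monomorphic, 1)
  expect_equal(rep_$n_removed_hwe, 1)
  expect_equal(rep_$n_removed_maf, 1)
  expect_equal(rep_$n_removed_pruning, 1)
  expect_equal(rep_$n_retained, 15)
  log <- rep_$removal_log
  expect_identical(log$stage[match(fails$variant_id, log$variant_id)],
                   c("callrate", "monomorphic", "hwe", "maf", "pruning"))

  # a clean dataset passes untouched
  clean <- run_qc(d)$report
  expect_equal(clean$n_retained, clean$n_input)
})

test_that("QC report conserves counts on random fixtures", {
  for (seed in c(41, 42)) {
    d <- random_ds(150, 25, seed = seed, miss = 0.08, maf_hi = 0.3)
    rep_ <- run_qc(d)$report
    removed <- rep_$n_removed_callrate + rep_$n_removed_monomorphic +
      rep_$n_removed_hwe + rep_$n_removed_maf + rep_$n_removed_pruning
    expect_equal(rep_$n_input - removed, rep_$n_retained)
    expect_equal(nrow(rep_$removal_log), removed)
  }
})
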