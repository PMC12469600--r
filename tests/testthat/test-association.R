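test_that("allelic odds ratio matches hand arithmetic", {
  res <- allelic_odds_ratio(10, 90, 5, 95)
  expect_equal(res$odds_ratio, 950 / 450, tolerance = 1e-12)
  expect_equal(res$log_or, log(950 / 450), tolerance = 1e-12)

  eq <- allelic_odds_ratio(30, 70, 60, 140)  # equal allele frequencies
  expect_equal(eq$odds_ratio, 1, tolerance = 1e-12)
  expect_equal(eq$log_or, 0, tolerance = 1e-12)

  # zero cell triggers the Haldane-Anscombe correction on all four cells
  hz <- allelic_odds_ratio(0, 100, 10, 90)
  expect_equal(hz$odds_ratio, (0.5 * 90.5) / (100.5 * 10.5), tolerance = 1e-12)
  expect_true(is.finite(hz$log_or))

  expect_error(allelic_odds_ratio(0, 0, 5, 5), "zero observed alleles")
  expect_error(allelic_odds_ratio(-1, 5, 5, 5), "non-negative")
})

test_that("odds ratio obeys inversion symmetry and scale invariance", {
  set.seed(51)
  for (i in 1:25) {
    cells <- sample(1:400, 4)
    f <- allelic_odds_ratio(cells[1], cells[2], cells[3], cells[4])
    r <- allelic_odds_ratio(cells[3], cells[4], cells[1], cells[2])
    expect_equal(f$odds_ratio * r$odds_ratio, 1, tolerance = 1e-12)
    dbl <- allelic_odds_ratio(2 * cells[1], 2 * cells[2], 2 * cells[3],
                              2 * cells[4])
    expect_equal(dbl$odds_ratio, f$odds_ratio, tolerance = 1e-12)
  }
})

test_that("variants rank by raw OR, by |log OR| on request, ties stable", {
  # build genotypes whose allele-count ORs are about 2.0, 0.4, 1.5
  d <- make_ds(rbind(
    c(2L, 0L, 1L), c(2L, 0L, 2L), c(1L, 1L, 1L), c(1L, 0L, 1L),
    c(0L, 1L, 0L), c(1L, 2L, 1L), c(0L, 2L, 0L), c(1L, 1L, 0L)),
    phenotype = c(rep("case", 4), rep("control", 4)))
  rk <- rank_variants(d)
  expect_true(all(diff(rk$odds_ratio) <= 0))
  expect_identical(rk$rank, 1:3)

  rk2 <- rank_variants(d, ranking_key = "abs_log_or")
  expect_true(all(diff(abs(rk2$log_or)) <= 1e-12))

  # identical variants tie -> original index order preserved
  g <- cbind(c(2L, 2L, 0L, 0L), c(2L, 2L, 0L, 0L), c(1L, 1L, 1L, 1L))
  dt <- make_ds(g, c("case", "case", "control", "control"))
  rkt <- rank_variants(dt)
  expect_identical(rkt$variant_id[1:2], c("v001", "v002"))

  expect_error(rank_variants(make_ds(g, rep("case", 4))), "no controls")
})

test_that("the polygenic score matches its defining formula", {
  # N = 2, ORs (2, 0.5), dosages (2, 1): (2 log2 + 1 log0.5) / 4
  d <- make_ds(rbind(c(2L, 1L), c(0L, 0L)), c("case", "control"))
  sel <- data.frame(variant_id = c("v001", "v002"), log_or = log(c(2, 0.5)))
  prof <- compute_prs(d, sel)
  expect_equal(prof$score[1], (2 * log(2) + log(0.5)) / 4, tolerance = 1e-9)
  expect_equal(prof$score[1], 0.17329, tolerance = 1e-4)
  expect_equal(prof$score[2], 0)  # all dosages 0

  # all selected ORs = 1 -> every score 0
  sel1 <- data.frame(variant_id = c("v001", "v002"), log_or = c(0, 0))
  expect_true(all(compute_prs(d, sel1)$score == 0))
})

test_that("scores are invariant to variant order and match a loop oracle", {
  d <- random_ds(25, 12, seed = 61, miss = 0)
  rk <- rank_variants(d)
  sel <- head(rk, 8)
  p1 <- compute_prs(d, sel, denominator_mode = "fixed")
  p2 <- compute_prs(d, sel[sample(8), ], denominator_mode = "fixed")
  expect_equal(p1$score, p2$score, tolerance = 1e-12)

  # brute-force per-individual loop
  idx <- match(sel$variant_id, d$variants$variant_id)
  oracle <- sapply(seq_len(25), function(j) {
    sum(sel$log_or * d$genotypes[j, idx]) / (2 * 8)
  })
  expect_equal(p1$score, oracle, tolerance = 1e-12)
})

test_that("missing genotypes use the per-individual denominator by default", {
  d <- make_ds(rbind(c(2L, NA), c(NA, NA)), c("case", "control"))
  sel <- data.frame(variant_id = c("v001", "v002"), log_or = c(log(3), log(2)))
  prof <- compute_prs(d, sel)
  expect_equal(prof$score[1], 2 * log(3) / 2, tolerance = 1e-12)  # N_j = 1
  expect_true(is.na(prof$score[2]))  # every selected genotype missing

  fixed <- compute_prs(d, sel, denominator_mode = "fixed")
  expect_equal(fixed$score[1], 2 * log(3) / 4, tolerance = 1e-12)

  expect_error(compute_prs(d, data.frame(variant_id = "nope", log_or = 1)),
               "absent")
})

test_that("max-T permutation test flags a planted strong effect", {
  set.seed(71)
  n_case <- 200; n_ctrl <- 200
  m <- 51
  g <- matrix(rbinom((n_case + n_ctrl) * m, 2, 0.3), n_case + n_ctrl, m)
  # variant 1: allele frequency 0.5 in cases vs 0.1 in controls
  g[, 1] <- c(rbinom(n_case, 2, 0.5), rbinom(n_ctrl, 2, 0.1))
  d <- make_ds(g, c(rep("case", n_case), rep("control", n_ctrl)))
  res <- permutation_test(d, n_perms = 1000, seed = 72)
  expect_lte(res$p_adjusted[1], 0.05)
  expect_true(all(res$p_adjusted >= 1 / 1001))
})

test_that("permutation p-values use the add-one estimator", {
  d <- random_ds(30, 5, seed = 81, miss = 0)
  res <- permutation_test(d, n_perms = 1, seed = 82)
  expect_true(all(res$p_adjusted %in% c(0.5, 1)))
  expect_true(all(res$p_adjusted > 0))
  const <- make_ds(matrix(rbinom(40, 2, 0.3), 20, 2), rep("case", 20))
  expect_error(permutation_test(const, n_perms = 10, seed = 1), "constant")
})

test_that("family-wise error is controlled under the null", {
  set.seed(91)
  n_rej <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    g <- matrix(rbinom(60 * 15, 2, 0.3), 60, 15)
    d <- make_ds(g, sample(rep(c("case", "control"), 30)))
    res <- permutation_test(d, n_perms = 200, seed = 1000 + r)
    if (any(res$p_adjusted < 0.05)) n_rej <- n_rej + 1L
  }
  # familywise rejection probability should be at most ~alpha
  expect_lte(n_rej / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
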