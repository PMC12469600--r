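test_that("control threshold follows the linear-interpolation quantile", {
  expect_equal(control_threshold(1:100, rep(TRUE, 100)), 95.05,
               tolerance = 1e-12)
  expect_equal(control_threshold(rep(3.2, 10), rep(TRUE, 10)), 3.2)
  expect_equal(control_threshold(c(5, 1, 9, 2), rep(TRUE, 4), percentile = 100), 9)
  # nearest-rank convention
  expect_equal(control_threshold(1:100, rep(TRUE, 100), type = "nearest_rank"),
               unname(quantile(1:100, 0.95, type = 1)))
  expect_error(control_threshold(numeric(0), logical(0)), "no control")
})

test_that("classification is strict at the threshold", {
  expect_identical(classify(c(1, 2, 2 + 1e-12, NA), threshold = 2),
                   c("control", "control", "case", NA))
  expect_error(classify(1:3, Inf), "finite")
})

test_that("decision table reproduces the published confusion counts", {
  # 384 cases all predicted case; 26 of 548 controls predicted case
  tab <- prediction_table_from_counts(384, 0, 26, 522)
  expect_equal(tab$misclassified, 26)
  expect_equal(tab$misclassification_rate, 26 / 932, tolerance = 1e-12)
  expect_equal(round(100 * tab$misclassification_rate, 1), 2.8)
  expect_equal(tab$ppv, 384 / 410, tolerance = 1e-12)
  expect_equal(tab$npv, 1, tolerance = 1e-12)
  expect_equal(tab$acc, 906 / 932, tolerance = 1e-12)
  expect_true(tab$or_infinite)
})

test_that("decision table handles degenerate and symmetric cases", {
  perf <- prediction_table_from_counts(10, 0, 0, 10)
  expect_equal(perf$acc, 1)
  expect_true(perf$or_infinite)

  sym <- prediction_table_from_counts(10, 10, 10, 10)
  expect_equal(sym$ppv, 0.5)
  expect_equal(sym$npv, 0.5)
  expect_equal(sym$acc, 0.5)
  expect_equal(sym$odds_ratio, 1)

  # no controls: control-side metrics are NA, never NaN
  noc <- prediction_table(rep("case", 4), rep("case", 4))
  expect_true(is.na(noc$fpr) && is.na(noc$npv))
  expect_false(any(sapply(noc[c("ppv", "npv", "acc", "fpr")],
                          function(v) is.nan(v))))
})

test_that("counts from labels agree and exclusions are tallied", {
  pred <- c("case", "control", NA, "case", "control")
  truth <- c("case", "case", "control", "control", "missing")
  tab <- prediction_table(pred, truth)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 0))
  expect_equal(tab$n_excluded, 2)
})

test_that("OR identity holds for random positive-cell tables", {
  set.seed(101)
  for (i in 1:30) {
    x <- sample(1:200, 4)
    tab <- prediction_table_from_counts(x[1], x[2], x[3], x[4])
    lhs <- (x[1] * x[4]) / (x[2] * x[3])
    rhs <- tab$ppv * tab$npv / ((1 - tab$ppv) * (1 - tab$npv))
    expect_equal(tab$odds_ratio, lhs, tolerance = 1e-12)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("sweep at a single N equals the direct pipeline composition", {
  d <- random_ds(40, 5, seed = 111, miss = 0)
  rk <- rank_variants(d)
  sw <- sweep_grid(d, rk, grid = 5)
  prof <- compute_prs(d, head(rk, 5))
  thr <- control_threshold(prof)
  tab <- prediction_table(classify(prof, thr), prof$phenotype)
  expect_equal(sw$tables[[1]]$a, tab$a)
  expect_equal(sw$tables[[1]]$acc, tab$acc)
  expect_equal(sw$tpr[1], tab$tpr)
  expect_equal(sw$fpr[1], tab$fpr)
  expect_warning(sweep_grid(d, rk, grid = c(5, 50)), "clipped")
})

test_that("more true effect variants improve sweep accuracy", {
  cfg <- sim_config(n_male = 500, n_female = 500, n_variants = 500,
                    n_effect_shared = 20, n_effect_male = 0,
                    n_effect_female = 0, effect_log_or_range = c(1.0, 1.2),
                    missing_rate = 0, seed = 112)
  d <- simulate_cohort(cfg)
  rk <- rank_variants(d)
  sw <- sweep_grid(d, rk, grid = c(5, 20))
  expect_gt(sw$tables[[2]]$acc, sw$tables[[1]]$acc)
})

test_that("ROC smoothing fixes a dip and leaves conforming series alone", {
  ok <- list(tpr = c(0.3, 0.5, 0.9), fpr = c(0.05, 0.2, 0.4))
  sm <- smooth_roc(ok)
  expect_equal(sm$smoothed_tpr, ok$tpr)
  expect_equal(sm$smoothed_fpr, ok$fpr)
  expect_equal(attr(sm, "iterations"), 0L)

  dip <- list(tpr = c(0.2, 0.1, 0.4), fpr = c(0.0, 0.05, 0.1))
  sm2 <- smooth_roc(dip)
  expect_equal(sm2$smoothed_tpr, c(0.2, (0.2 + 0.1 + 0.4) / 3, 0.4),
               tolerance = 1e-12)

  const <- list(tpr = rep(0.4, 5), fpr = rep(0.4, 5))
  sm3 <- smooth_roc(const)
  expect_equal(sm3$smoothed_tpr, const$tpr)
  expect_equal(sm3$auc, 0.5, tolerance = 1e-12)

  bad <- list(tpr = c(0, 0.1, 0.2), fpr = c(0.5, 0.6, 0.7))
  expect_error(smooth_roc(bad, max_iter = 50), "iterations")
})

test_that("smoothed output always satisfies both ROC conditions", {
  set.seed(121)
  for (i in 1:20) {
    fpr <- sort(runif(9, 0, 0.6))
    tpr <- pmin(1, pmax(0, fpr + runif(9, -0.05, 0.5)))
    tpr[1] <- max(tpr[1], fpr[1])          # conforming endpoints so the
    tpr[9] <- max(c(tpr, fpr))             # fixed-point iteration can land
    sm <- smooth_roc(list(tpr = tpr, fpr = fpr), max_iter = 5000)
    expect_true(all(sm$smoothed_tpr >= sm$smoothed_fpr - 1e-9))
    ord <- order(sm$smoothed_fpr)
    expect_true(all(diff(sm$smoothed_tpr[ord]) >= -1e-9))
    expect_gte(sm$auc, 0.5 - 1e-9)
  }
})

test_that("AUC by trapezoid matches hand sums", {
  expect_equal(compute_auc(list(tpr = 1, fpr = 0)), 1)
  expect_equal(compute_auc(list(tpr = c(0.2, 0.7), fpr = c(0.2, 0.7))), 0.5)
  # (0,0) -> (0.2,0.6) -> (0.5,0.9) -> (1,1)
  expect_equal(compute_auc(list(tpr = c(0.6, 0.9), fpr = c(0.2, 0.5))),
               0.2 * 0.3 + 0.3 * 0.75 + 0.5 * 0.95, tolerance = 1e-12)
  # duplicated FPR values are averaged
  expect_equal(compute_auc(list(tpr = c(0.4, 0.6), fpr = c(0.3, 0.3))),
               compute_auc(list(tpr = 0.5, fpr = 0.3)), tolerance = 1e-12)
})

test_that("an all-null cohort classifies at the analytic rate", {
  cfg <- sim_config(n_male = 300, n_female = 300, n_variants = 80,
                    n_effect_male = 0, n_effect_female = 0,
                    n_effect_shared = 0, prevalence_target = 0.337,
                    missing_rate = 0, seed = 131)
  d <- simulate_cohort(cfg)
  rk <- rank_variants(d)
  sw <- sweep_grid(d, rk, grid = c(10, 40, 80))
  n_case <- sum(d$samples$phenotype == "case")
  n_ctrl <- sum(d$samples$phenotype == "control")
  expected_acc <- (0.05 * n_case + 0.95 * n_ctrl) / (n_case + n_ctrl)
  for (tab in sw$tables) {
    expect_lt(abs(tab$acc - expected_acc), 0.06)
    expect_lt(abs(tab$fpr - 0.05), 0.03)  # threshold calibration
  }
})
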