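# Statistical procedures against enumeration oracles and worked examples.

test_that("risk classification implements the histology rule", {
  expect_equal(classify_risk("endometrioid", 1), "low")
  expect_equal(classify_risk("endometrioid", 2), "low")
  expect_equal(classify_risk("endometrioid", 3), "high")
  expect_equal(classify_risk("nonendometrioid"), "high")
  expect_equal(classify_risk("endometrioid", 2, dmi = TRUE), "high")
  expect_equal(classify_risk("endometrioid", 1, lvsi = TRUE), "high")
  expect_equal(classify_risk("endometrioid", 1, lnm = TRUE), "high")
  expect_error(classify_risk("endometrioid"), "grade")
  expect_error(classify_risk("serous"), "unknown subtype")
})

test_that("Mann-Whitney matches exact enumeration for small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_raw, 0.100, tolerance = 1e-9)
  set.seed(101)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(mann_whitney_u(x, y)$p_raw, bf_mann_whitney_p(x, y),
                 tolerance = 1e-9)
  }
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$p_raw, 1.0)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Wilcoxon signed-rank matches sign-assignment enumeration", {
  expect_equal(wilcoxon_signed_rank(1:5)$p_raw, 0.0625, tolerance = 1e-9)
  expect_equal(wilcoxon_signed_rank(c(-2, -1, 1, 2))$p_raw, 1.0)
  d0 <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(d0$degenerate)
  expect_equal(d0$p_raw, 1.0)
  set.seed(202)
  for (i in 1:5) {
    d <- rnorm(6)
    expect_equal(wilcoxon_signed_rank(d)$p_raw, bf_signed_rank_p(d),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up definition and is monotone", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04), rep("a", 4)),
               rep(0.04, 4))
  expect_equal(fdr_adjust(0.3, "a"), 0.3)
  set.seed(303)
  for (i in 1:10) {
    p <- runif(7)
    adj <- fdr_adjust(p, rep("fam", 7))
    expect_equal(adj, bf_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))     # monotone in ranks
  }
  # families are adjusted independently
  p <- c(0.01, 0.04, 0.02, 0.03)
  fam <- c("a", "a", "b", "b")
  expect_equal(fdr_adjust(p, fam),
               c(bf_bh(p[1:2]), bf_bh(p[3:4])))
})

test_that("largest raw p within a family is left unchanged by BH", {
  # the published model-family p values; < 0.001 entries represented small
  et <- c(5e-4, 5e-4, 0.39, 5e-4)
  dp <- c(5e-4, 0.08, 5e-4, 0.61, 5e-4, 0.52)
  adj <- fdr_adjust(c(et, dp), c(rep("et", 4), rep("dp", 6)))
  expect_identical(adj[3], 0.39)
  expect_identical(adj[8], 0.61)
})

test_that("Spearman matches the rank formula and permutation p-values", {
  expect_equal(spearman_cor(1:5, (1:5)^2)$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  set.seed(404)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    s <- spearman_cor(x, y)
    rx <- rank(x); ry <- rank(y)
    rho_formula <- 1 - 6 * sum((rx - ry)^2) / (5 * 24)
    expect_equal(s$rho, rho_formula, tolerance = 1e-12)
    expect_equal(s$p, bf_spearman_p(x, y), tolerance = 1e-9)
  }
  expect_true(spearman_cor(rep(1, 5), 1:5)$flagged)
})

test_that("Bland-Altman reproduces the worked example and trend semantics", {
  r <- bland_altman(c(1.1, 2.2, 3.3), c(1.0, 2.0, 3.0))
  expect_equal(r$bias, 0.2, tolerance = 1e-12)
  expect_equal(r$loa_low, 0.2 - 1.96 * 0.1, tolerance = 1e-9)
  expect_equal(r$loa_high, 0.2 + 1.96 * 0.1, tolerance = 1e-9)
  same <- bland_altman(1:5, 1:5)
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  expect_true(same$trend_flagged)
  shifted <- bland_altman(1:6 + 2, as.numeric(1:6))
  expect_true(shifted$trend_flagged || abs(shifted$trend_rho) < 1e-9)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("ROC analysis is confusion-table consistent and equals U/(n1 n2)", {
  set.seed(505)
  lo <- rnorm(12, 1); hi <- rnorm(13, 0)   # positive class lower
  vals <- c(lo, hi)
  labs <- c(rep("low", 12), rep("high", 13))
  r <- roc_analysis(vals, labs, "high")
  expect_equal(r$orientation, "<=")
  expect_equal(r$auc, bf_auc(hi, lo), tolerance = 1e-12)  # flipped class AUC
  # metrics recompute exactly from the confusion table at the cutoff
  pred <- vals <= r$cutoff
  truth <- labs == "high"
  expect_equal(r$sensitivity, 100 * mean(pred[truth]))
  expect_equal(r$specificity, 100 * mean(!pred[!truth]))
  expect_equal(r$accuracy, 100 * mean(pred == truth))
  # perfect separation
  rp <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c("high", "low"), each = 3))
  expect_equal(rp$auc, 1.0)
  expect_equal(rp$youden, 1.0)
  # identical values
  r5 <- roc_analysis(rep(1, 6), rep(c("high", "low"), 3))
  expect_equal(r5$auc, 0.5)
  expect_error(roc_analysis(1:3, rep("high", 3)), "both classes")
})

test_that("DeLong interval agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(606)
  vals <- c(rnorm(20, 1), rnorm(20, 0))
  labs <- rep(c("high", "low"), each = 20)
  r <- roc_analysis(vals, labs, "high")
  ref <- pROC::ci.auc(pROC::roc(labs, vals, levels = c("low", "high"),
                                direction = "<", quiet = TRUE),
                      method = "delong")
  expect_equal(r$auc, as.numeric(ref[2]), tolerance = 1e-9)
  expect_equal(r$auc_ci_low, as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(r$auc_ci_high, as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("McNemar matches the closed-form binomial", {
  # b=1, c=8: p = 2 * (C(9,0)+C(9,1)) / 2^9 = 20/512
  a_correct <- c(rep(TRUE, 1), rep(FALSE, 8), rep(TRUE, 10))
  b_correct <- c(rep(FALSE, 1), rep(TRUE, 8), rep(TRUE, 10))
  r <- mcnemar_paired(a_correct, b_correct)
  expect_equal(r$p_raw, 20 / 512, tolerance = 1e-12)
  expect_equal(c(r$b, r$c), c(1, 8))
  r2 <- mcnemar_paired(c(rep(TRUE, 3), rep(FALSE, 3)),
                       c(rep(FALSE, 3), rep(TRUE, 3)))
  expect_equal(r2$p_raw, 1.0)
  r0 <- mcnemar_paired(rep(TRUE, 5), rep(TRUE, 5))
  expect_true(r0$degenerate)
  expect_equal(r0$p_raw, 1.0)
})

test_that("ICC(2,1) matches an independent reference value and categories", {
  r1 <- c(8.1, 6.2, 9.5, 5.0)
  r2 <- c(7.9, 6.8, 9.1, 5.6)
  r <- icc_two_reader(r1, r2)
  expect_equal(r$icc, 0.962763, tolerance = 1e-5)  # two-way random, absolute
  expect_equal(r$category, "excellent")
  expect_equal(icc_two_reader(r1, r1)$icc, 1)
  expect_equal(icc_two_reader(c(1, 2, 3, 4), c(1, 2, 3, 4))$category,
               "excellent")
  expect_true(icc_two_reader(rep(2, 4), rep(2, 4))$flagged)
})

test_that("median CI covers at the nominal rate at n = 25", {
  set.seed(707)
  hits <- 0L
  for (i in 1:1000) {
    x <- rnorm(25)
    ci <- median_ci(x)
    if (ci$ci_low <= 0 && 0 <= ci$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / 1000, 0.93)
})

test_that("exclusion accounting reproduces the recruitment flow", {
  roster <- synthetic_roster(112, c(33, 9, 7, 6, 6), seed = 4)
  res <- apply_exclusions(roster)
  expect_equal(res$n_kept, 51)
  expect_equal(unname(res$counts), c(33, 9, 7, 6, 6))
  expect_equal(nrow(res$excluded), 61)
  expect_false(any(duplicated(res$excluded$id)))
  expect_error(apply_exclusions(roster[, 1:3]), "lacks column")
})
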