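test_that("confusion matrices count the four cells correctly", {
  truth <- c("BD", "BD", "HC", "HC", "HC")
  cm <- confusion_matrix(truth, truth, "BD")
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(2, 0, 0, 3))
  flip <- ifelse(truth == "BD", "HC", "BD")
  cm2 <- confusion_matrix(flip, truth, "BD")
  expect_equal(c(cm2$tp, cm2$tn), c(0, 0))
  expect_equal(cm2$fn + cm2$fp, 5)
  expect_error(confusion_matrix(c("BD", "XX"), truth[1:2], "BD"), "unknown")
  expect_error(confusion_matrix(truth[1:3], truth, "BD"), "equal length")
})

test_that("diagnostic metrics reproduce the published table rows", {
  # BD-I vs matched controls, reconstructed counts
  m1 <- diagnostic_metrics(
    confusion_matrix(rep(c("BD", "HC", "BD", "HC"), c(9, 14, 5, 28)),
                     rep(c("BD", "HC"), c(23, 33)), "BD"))
  expect_equal(round_half_up(m1$accuracy, 1), 66.1)
  expect_equal(round_half_up(m1$ppv, 1), 64.3)
  # MDD vs matched controls
  m2 <- diagnostic_metrics(
    confusion_matrix(rep(c("MDD", "HC", "MDD", "HC"), c(6, 13, 10, 28)),
                     rep(c("MDD", "HC"), c(19, 38)), "MDD"))
  expect_equal(round_half_up(m2$accuracy, 1), 59.6)
  expect_equal(round_half_up(m2$ppv, 1), 37.5)
  expect_equal(round_half_up(m2$npv, 1), 68.3)
  # degenerate: all positives predicted positive, no negatives at all
  m3 <- diagnostic_metrics(confusion_matrix(rep("BD", 5), rep("BD", 5),
                                            "BD"))
  expect_equal(m3$accuracy, 100)
  expect_true(is.na(m3$specificity))
  expect_true(is.na(m3$npv))
})

test_that("ROC curves are valid staircases with the expected points", {
  s <- c(0.9, 0.7, 0.3, 0.8, 0.2)
  tr <- c("P", "P", "P", "N", "N")
  rc <- roc_curve(s, tr, "P")
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_true(any(abs(rc$fpr - 0.5) < 1e-12 & abs(rc$tpr - 2 / 3) < 1e-12))
  # perfect ranking passes through (0, 1)
  rp <- roc_curve(c(3, 2, 1), c("P", "P", "N"), "P")
  expect_true(any(rp$fpr == 0 & rp$tpr == 1))
  # reversing score signs reflects the curve across the diagonal: the
  # reflected vertices all lie on the reversed staircase, and AUC flips
  rr <- roc_curve(-s, tr, "P")
  expect_true(all(diff(rr$fpr) >= 0) && all(diff(rr$tpr) >= 0))
  expect_equal(auc_score(-s, tr, "P"), 1 - auc_score(s, tr, "P"))
  expect_warning(roc_curve(rep(1, 5), tr, "P"), "constant")
})

test_that("AUC equals the concordant-pair probability", {
  s <- c(0.9, 0.7, 0.3, 0.8, 0.2)
  tr <- c("P", "P", "P", "N", "N")
  expect_equal(auc_score(s, tr, "P"), 4 / 6)
  expect_equal(auc_score(c(3, 2, 1), c("P", "P", "N"), "P"), 1)
  # ties are half-concordant
  expect_equal(auc_score(c(1, 1), c("P", "N"), "P"), 0.5)

  # trapezoidal integration agrees with the rank statistic on random data
  set.seed(13)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    sc <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    lab <- sample(c("P", "N"), n, TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(auc_score(sc, lab, "P", "trapezoid"),
                 auc_score(sc, lab, "P", "rank"), tolerance = 1e-12)
  }

  # independent oracle: pROC on a handful of instances
  set.seed(14)
  for (i in 1:10) {
    sc <- rnorm(20)
    lab <- rep(c("P", "N"), 10)
    expect_equal(auc_score(sc, lab, "P"),
                 as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("N", "P"),
                                                direction = "<", quiet = TRUE))))
  }

  # permutation null centred at one half
  set.seed(15)
  a <- replicate(1000, auc_score(rnorm(20), sample(rep(c("P", "N"), 10)), "P"))
  expect_lt(abs(mean(a) - 0.5), 0.02)
})

test_that("the best threshold maximizes accuracy with spec tie-breaking", {
  s <- c(0.9, 0.7, 0.3, 0.8, 0.2)
  tr <- c("P", "P", "P", "N", "N")
  bt <- best_threshold(s, tr, "P")
  expect_equal(bt$report$accuracy, 80)
  # exhaustive-sweep oracle
  accs <- vapply(c(sort(unique(s)), Inf), function(th) {
    mean((s >= th) == (tr == "P"))
  }, numeric(1))
  expect_equal(bt$report$accuracy, 100 * max(accs))
  # separable scores reach 100%
  expect_equal(best_threshold(c(2, 3, 0, 1), c("P", "P", "N", "N"),
                              "P")$report$accuracy, 100)
  # degenerate constant scores fall back to the majority class
  bt0 <- best_threshold(rep(1, 5), tr, "P")
  expect_equal(bt0$report$accuracy, 60)
  # accuracy at the best threshold is never below the majority fraction
  set.seed(16)
  for (i in 1:20) {
    sc <- rnorm(15); lab <- sample(c("P", "N"), 15, TRUE, c(.3, .7))
    if (length(unique(lab)) < 2) next
    maj <- 100 * max(mean(lab == "P"), mean(lab == "N"))
    expect_gte(best_threshold(sc, lab, "P")$report$accuracy, maj)
  }
})

test_that("feature frequency maps count selection fractions", {
  shape <- c(4, 4, 4)
  always <- 1:4
  sometimes <- 20:22
  folds <- lapply(1:10, function(i) {
    sel <- list(always)
    if (i <= 7) sel <- c(sel, list(sometimes))
    sel
  })
  fm <- feature_frequency(folds, shape)
  expect_true(all(fm[always] == 1))
  expect_true(all(fm[sometimes] == 0.7))
  expect_true(all(fm[30:64] == 0))
  expect_true(all(fm >= 0 & fm <= 1))
  expect_error(feature_frequency(list(), shape), "at least one")
})

test_that("leave-one-out produces one leakage-free prediction per subject", {
  co <- tiny_cohort(seed = 20, n = 5, d = 3, shape = c(10, 10, 10))
  res <- loocv_compare(co, "BD", "HC")
  expect_length(res$scores, 10)
  expect_length(res$predicted, 10)
  expect_false(anyNA(res$scores))
  # pooled scores are Z standardized
  expect_equal(mean(res$scores), 0, tolerance = 1e-12)
  expect_equal(sd(res$scores), 1, tolerance = 1e-12)
  # a strong planted effect is recovered
  expect_gte(res$accuracy, 0.8)
  expect_gte(res$auc, 0.8)
  # per-fold feature counts recorded; frequency map in range
  expect_length(res$n_selected, 10)
  expect_true(all(res$frequency >= 0 & res$frequency <= 1))
  expect_gt(max(res$frequency), 0.5)

  small <- tiny_cohort(seed = 21, n = 2, shape = c(10, 10, 10))
  expect_error(loocv_compare(small, "BD", "HC"), "at least 3")
})
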