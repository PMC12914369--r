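test_that("confusion matrices count paired decisions", {
  cm <- build_confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]), c(tp = 1, fp = 1, fn = 1, tn = 1))
  all_ok <- build_confusion(rep(c(TRUE, FALSE), c(10, 10)),
                            rep(c(TRUE, FALSE), c(10, 10)))
  expect_equal(unlist(all_ok[c("tp", "tn", "fp", "fn")]), c(tp = 10, tn = 10, fp = 0, fn = 0))
  expect_error(build_confusion(logical(0), logical(0)), "empty")
  expect_error(build_confusion(c(TRUE, FALSE), TRUE), "length")
})

test_that("metric formulas and identities hold", {
  cm <- confusion_matrix(tp = 85, fp = 28, fn = 15, tn = 72)
  rep <- metric_report(cm)
  expect_equal(rep$sensitivity, 0.85)
  expect_equal(rep$specificity, 0.72)
  expect_equal(rep$dor, (85 * 72) / (28 * 15))
  set.seed(31)
  for (i in 1:50) {
    cells <- sample(1:80, 4, replace = TRUE)
    r <- metric_report(confusion_matrix(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(r$youden, r$sensitivity + r$specificity - 1)
    expect_equal(r$dor, r$lr_pos / r$lr_neg, tolerance = 1e-12)
    expect_equal(r$auc, (r$sensitivity + r$specificity) / 2)
    if (r$youden >= 0) expect_true(r$auc >= 0.5 && r$auc <= 1)
  }
  # perfect classifier: youden 1, DOR undefined without correction
  perf <- confusion_matrix(tp = 12, fp = 0, fn = 0, tn = 9)
  expect_equal(metric_report(perf, "none")$youden, 1)
  expect_true(is.na(metric_report(perf, "none")$dor))
  expect_true(is.finite(metric_report(perf, "haldane_half")$dor))
  # chance classifier
  chance <- metric_report(confusion_matrix(25, 25, 25, 25))
  expect_equal(chance$sensitivity, 0.5)
  expect_equal(chance$youden, 0)
  expect_equal(chance$phi, 0)
})

test_that("phi is symmetric under swapping rule and reference labels", {
  set.seed(17)
  for (i in 1:20) {
    d <- runif(30) < 0.5; r <- runif(30) < 0.6
    if (length(unique(d)) < 2 || length(unique(r)) < 2) next
    expect_equal(metric_report(build_confusion(d, r))$phi,
                 metric_report(build_confusion(r, d))$phi)
  }
})

test_that("rank AUC equals the all-pairs oracle", {
  expect_equal(score_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(score_auc(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_equal(score_auc(c(2, 3, 3, 1, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE)),
               oracle_auc(c(2, 3, 3), c(1, 3)))
  expect_error(score_auc(1:3, c(TRUE, TRUE, TRUE)), "case and one control")
  set.seed(41)
  for (i in 1:15) {
    n <- sample(10:200, 1)
    ref <- runif(n) < 0.4
    if (!any(ref) || all(ref)) next
    scores <- sample(0:18, n, replace = TRUE) # tie-rich integer scores
    expect_equal(score_auc(scores, ref), oracle_auc(scores[ref], scores[!ref]),
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(43)
  ref <- runif(120) < 0.5
  scores <- rnorm(120) + ref
  expect_equal(score_auc(scores, ref),
               as.numeric(pROC::auc(pROC::roc(ref, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("metric confidence intervals contain their point estimates", {
  cm <- confusion_matrix(tp = 85, fp = 28, fn = 15, tn = 72)
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    ci <- metric_ci(cm, m)
    pt <- metric_report(cm)[[m]]
    expect_true(ci["lower"] <= pt && pt <= ci["upper"])
  }
  half <- metric_ci(confusion_matrix(10, 5, 10, 5), "sensitivity")
  expect_true(half["lower"] < 0.5 && half["upper"] > 0.5)
  # Wilson at x = n: upper bound exactly 1, lower below 1
  edge <- metric_ci(confusion_matrix(tp = 100, fp = 10, fn = 0, tn = 40), "sensitivity")
  expect_equal(unname(edge["upper"]), 1)
  expect_lt(edge["lower"], 1)
  dor_ci <- metric_ci(cm, "dor")
  expect_true(dor_ci["lower"] <= 14.57143 && 14.57143 <= dor_ci["upper"])
  expect_error(metric_ci(cm, "volume"), "unknown")
})

test_that("rule sweeps rank candidate rules by Youden index", {
  set.seed(19)
  co <- generate_diagnostic_cohort(cohort_params(n_cases = 60, n_controls = 60), seed = 19)
  rules <- list(
    diagnostic_rule("ACSS6", 6, TRUE, FALSE, name = "symptoms"),
    diagnostic_rule("ACSS6", 6, TRUE, TRUE, name = "symptoms+pyuria"),
    diagnostic_rule("ACSS6", 6, TRUE, TRUE, name = "dup")
  )
  tab <- rule_sweep(co$subjects, rules)
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$best) >= 1, TRUE)
  expect_equal(tab$youden[tab$best][1], max(tab$youden))
  # duplicate rules give identical rows
  expect_equal(tab$sensitivity[2], tab$sensitivity[3])
  expect_equal(tab$youden[2], tab$youden[3])
  expect_error(rule_sweep(co$subjects, list()), "empty")
  # an always-positive rule: sensitivity 1, specificity 0, youden 0
  always <- diagnostic_rule("ACSS6", 0, FALSE, FALSE, name = "always")
  row <- rule_sweep(co$subjects, list(always))
  expect_equal(row$sensitivity, 1)
  expect_equal(row$specificity, 0)
  expect_equal(row$youden, 0)
})

test_that("a dominating rule never has the lower Youden index", {
  # rule B dominates rule A by construction: same decisions plus extra
  # true positives and fewer false positives on a fixed 20-subject cohort
  ref <- rep(c(TRUE, FALSE), each = 10)
  a <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 4), rep(FALSE, 6))
  b <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  youden_a <- metric_report(build_confusion(a, ref))$youden
  youden_b <- metric_report(build_confusion(b, ref))$youden
  expect_gte(youden_b, youden_a)
})

test_that("adding the pyuria conjunct trades sensitivity for specificity", {
  set.seed(23)
  for (i in 1:25) {
    co <- generate_diagnostic_cohort(cohort_params(n_cases = 40, n_controls = 40),
                                     seed = 100 + i)
    sym <- diagnostic_rule("ACSS6", 6, TRUE, FALSE)
    both <- diagnostic_rule("ACSS6", 6, TRUE, TRUE)
    m1 <- metric_report(build_confusion(apply_rule(co$subjects, sym), co$subjects$reference))
    m2 <- metric_report(build_confusion(apply_rule(co$subjects, both), co$subjects$reference))
    expect_lte(m2$sensitivity, m1$sensitivity)
    expect_gte(m2$specificity, m1$specificity)
  }
})
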