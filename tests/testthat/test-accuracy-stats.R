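# Wilson intervals ------------------------------------------------------------

test_that("wilson_interval agrees with the score interval in prop.test", {
  for (n in c(5, 24, 173)) {
    for (k in 0:n) {
      got <- wilson_interval(k, n)
      ref <- suppressWarnings(prop.test(k, n, correct = FALSE)$conf.int)
      expect_equal(got$lower, ref[1], tolerance = 1e-10)
      expect_equal(got$upper, ref[2], tolerance = 1e-10)
    }
  }
})

test_that("wilson bounds contain the estimate, clamp to [0,1], shrink with n", {
  set.seed(9)
  for (i in 1:200) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    ci <- wilson_interval(k, n)
    expect_lte(ci$lower, ci$estimate)
    expect_gte(ci$upper, ci$estimate)
    expect_gte(ci$lower, 0)
    expect_lte(ci$upper, 1)
  }
  expect_identical(wilson_interval(0, 10)$lower, 0)
  expect_identical(wilson_interval(10, 10)$upper, 1)
  widths <- vapply(c(10, 100, 1000),
                   function(n) with(wilson_interval(3 * n / 10, n),
                                    upper - lower), numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("wilson intervals reproduce the published accuracy cells", {
  r2 <- function(x) round(x, 2)
  ci <- wilson_interval(13, 24)   # development sensitivity 0.54 (0.35-0.72)
  expect_equal(r2(ci$estimate), 0.54)
  expect_equal(r2(c(ci$lower, ci$upper)), c(0.35, 0.72))
  ci <- wilson_interval(23, 52)   # Australian sensitivity 0.44 (0.32-0.58)
  expect_equal(r2(c(ci$lower, ci$upper)), c(0.32, 0.58))
  ci <- wilson_interval(170, 173) # UK validation NPV 0.98 (0.95-0.99)
  expect_equal(r2(c(ci$lower, ci$upper)), c(0.95, 0.99))
  # insensitive to quantile truncation at this precision
  ci96 <- wilson_interval(13, 24, z_quantile = 1.96)
  expect_equal(r2(c(ci96$lower, ci96$upper)), c(0.35, 0.72))
})

# Confusion matrices -----------------------------------------------------------

test_that("confusion_matrix matches a brute-force tally and checks alignment", {
  records <- random_records(300, seed = 21)
  res <- pcsa_classify(records)
  res <- res[sample(nrow(res)), ]  # scrambled order must not matter
  cm <- confusion_matrix(res, records, positive = "suspicious")
  ref <- records$reference_suspicious[match(res$lesion_id,
                                            records$lesion_id)]
  test <- res$classification == "suspicious"
  expect_equal(cm$tp, sum(test & ref))
  expect_equal(cm$fp, sum(test & !ref))
  expect_equal(cm$fn, sum(!test & ref))
  expect_equal(cm$tn, sum(!test & !ref))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 300)

  dup <- rbind(res, res[1, ])
  expect_error(confusion_matrix(dup, records), "duplicate")
  res$lesion_id[1] <- "missing-id"
  expect_error(confusion_matrix(res, records), "unmatched")
})

test_that("degenerate classifiers give the forced confusion cells", {
  records <- random_records(150, seed = 22)
  perfect <- data.frame(
    lesion_id = records$lesion_id, algorithm = "oracle", gate = "none",
    score = as.integer(records$reference_suspicious),
    classification = ifelse(records$reference_suspicious, "suspicious",
                            "benign"), stringsAsFactors = FALSE)
  cm <- confusion_matrix(perfect, records)
  expect_equal(c(cm$fp, cm$fn), c(0L, 0L))
  allneg <- perfect
  allneg$classification <- "benign"
  cm <- confusion_matrix(allneg, records)
  expect_equal(cm$tp, 0L)
  expect_equal(cm$fn, sum(records$reference_suspicious))
})

test_that("diagnostic_summary reproduces the UK validation column and identities", {
  cm <- new_confusion_matrix(tp = 3, fp = 32, fn = 3, tn = 170)
  ds <- diagnostic_summary(cm)
  est <- setNames(ds$estimate, ds$statistic)
  expect_equal(unname(est), c(3 / 6, 170 / 202, 3 / 35, 170 / 173))
  expect_equal(round(unname(est), 2), c(0.50, 0.84, 0.09, 0.98))
  # algebraic identities on a random matrix
  cm <- new_confusion_matrix(17, 41, 8, 211)
  ds <- diagnostic_summary(cm)
  expect_equal(ds$estimate[ds$statistic == "sensitivity"] * (17 + 8), 17)
  expect_equal(ds$estimate[ds$statistic == "npv"] * (211 + 8), 211)
})

test_that("zero denominators yield explicit undefined markers, not NaN", {
  ds <- diagnostic_summary(new_confusion_matrix(0, 0, 4, 20))
  expect_true(ds$undefined[ds$statistic == "ppv"])
  expect_false(any(is.nan(ds$estimate)))
  ds <- diagnostic_summary(new_confusion_matrix(5, 3, 0, 0))
  expect_true(ds$undefined[ds$statistic == "npv"])
  perfect <- diagnostic_summary(new_confusion_matrix(7, 0, 0, 30))
  expect_equal(perfect$estimate, rep(1, 4))
})

# ROC --------------------------------------------------------------------------

test_that("ROC AUC is exact for separation, ties, and the pairwise oracle", {
  expect_equal(roc_curve(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_curve(rep(5, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  set.seed(31)
  for (i in 1:300) {
    n <- sample(10:150, 1)
    labels <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(labels) || all(labels)) next
    scores <- sample(0:8, n, replace = TRUE)
    roc <- roc_curve(scores, labels)
    expect_equal(roc$auc, mw_auc(scores, labels), tolerance = 1e-13)
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
    expect_equal(roc$points[nrow(roc$points), ], data.frame(fpr = 1, tpr = 1),
                 ignore_attr = TRUE)
  }
})

test_that("ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  for (i in 1:20) {
    labels <- runif(80) < 0.4
    if (!any(labels) || all(labels)) next
    scores <- rnorm(80) + labels
    got <- roc_curve(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("gated lesions are excluded or floored per policy", {
  scores <- c(5, 4, 1, 0, NA, NA)
  labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  gated <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  excl <- roc_curve(scores, labels, gated, "exclude")
  expect_equal(c(excl$n_pos, excl$n_neg), c(2, 2))
  expect_equal(excl$auc, 1)
  floored <- roc_curve(scores, labels, gated, "floor")
  expect_equal(c(floored$n_pos, floored$n_neg), c(3, 3))
  # the gated positive ranks below every negative: 6 of 9 pairs won, 1 tie
  expect_equal(floored$auc, mw_auc(c(5, 4, 1, 0, -1, -1), labels))
  expect_error(roc_curve(c(1, NA), c(TRUE, FALSE)), "NA score")
})

# Hanley-McNeil ----------------------------------------------------------------

test_that("hanley_mcneil_se collapses to its closed-form boundary values", {
  expect_equal(hanley_mcneil_se(1, 12, 99), 0)
  expect_equal(hanley_mcneil_se(0.5, 1, 1), 0.5)
  expect_equal(hanley_mcneil_se(0.83, 12, 99), 0.0747512, tolerance = 1e-5)
  # monotone decreasing in balanced n at chance performance
  ses <- vapply(c(5, 10, 50, 200), function(n) hanley_mcneil_se(0.5, n, n),
                numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_error(hanley_mcneil_se(1.2, 5, 5), "auc")
})

test_that("hanley_mcneil_se matches the sampling SD under its ROC model", {
  # bi-exponential scores: neg ~ Exp(1), pos ~ Exp(a), AUC = 1/(1+a)
  set.seed(33)
  a <- (1 - 0.83) / 0.83
  aucs <- replicate(2000, {
    scores <- c(rexp(12, a), rexp(99, 1))
    roc_curve(scores, rep(c(TRUE, FALSE), c(12, 99)))$auc
  })
  expect_equal(sd(aucs), hanley_mcneil_se(0.83, 12, 99), tolerance = 0.05)
})

test_that("correlated-AUC z-test limits: equal AUCs, r = 0, degenerate variance", {
  eq <- compare_correlated_auc(0.7, 0.7, 0.05, 0.08, 0.4)
  expect_equal(eq$z_statistic, 0)
  expect_equal(eq$p_value, 1)
  unpaired <- compare_correlated_auc(0.83, 0.61, 0.06, 0.09, 0)
  expect_equal(unpaired$z_statistic, (0.83 - 0.61) / sqrt(0.06^2 + 0.09^2))
  expect_equal(unpaired$p_value,
               2 * pnorm(-abs(unpaired$z_statistic)))
  expect_error(compare_correlated_auc(0.8, 0.7, 0.05, 0.05, 1),
               "non-positive variance")
})

test_that("compare_auc_paired assembles AUCs, SEs and the r surrogate", {
  set.seed(34)
  labels <- rep(c(TRUE, FALSE), c(30, 70))
  shared <- rnorm(100)
  s1 <- 1.2 * labels + 0.6 * shared + rnorm(100)
  s2 <- 1.2 * labels + 0.6 * shared + rnorm(100)
  cmp <- compare_auc_paired(s1, s2, labels)
  expect_equal(cmp$auc1, mw_auc(s1, labels))
  expect_equal(cmp$se1, hanley_mcneil_se(cmp$auc1, 30, 70))
  r_hand <- mean(c(cor(s1[labels], s2[labels]),
                   cor(s1[!labels], s2[!labels])))
  expect_equal(cmp$r, r_hand)
  expect_gt(cmp$r, 0)
  expect_equal(cmp$p_value, 2 * pnorm(-abs(cmp$z_statistic)))
})

# Reconstruction ----------------------------------------------------------------

test_that("the UK validation column inverts to a unique confusion matrix", {
  res <- reconstruct_confusion_matrix(208, 6, sens = 0.50, spec = 0.84,
                                      ppv = 0.09, npv = 0.98)
  expect_equal(nrow(res), 1)
  expect_equal(res$tp, 3)
  expect_equal(res$fp, 32)
  expect_equal(res$fn, 3)
  expect_equal(res$tn, 170)
})

test_that("a single printed sensitivity pins the true-positive count", {
  res <- reconstruct_confusion_matrix(422, 24, sens = 0.54)
  expect_gt(nrow(res), 1)
  expect_true(all(res$tp == 13))  # 13/24 is the unique rounding preimage
})

test_that("the Australian column is mutually inconsistent under every rule", {
  for (rule in c("half_up", "half_even", "truncate")) {
    res <- reconstruct_confusion_matrix(581, 52, sens = 0.44, spec = 0.95,
                                        ppv = 0.52, npv = 0.95,
                                        rounding = rule)
    expect_equal(nrow(res), 0)
  }
})

test_that("reconstruction is sound and complete against a brute-force oracle", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    npos <- sample(3:12, 1)
    tp <- sample(0:npos, 1)
    tn <- sample(0:(n - npos), 1)
    r2 <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100
    sens <- r2(tp / npos)
    spec <- r2(tn / (n - npos))
    got <- reconstruct_confusion_matrix(n, npos, sens = sens, spec = spec)
    # soundness: every returned matrix reproduces the printed values
    expect_true(all(r2(got$tp / npos) == sens))
    expect_true(all(r2(got$tn / (n - npos)) == spec))
    # completeness: agrees with the plain double-loop oracle, and the true
    # generating matrix is recovered
    oracle <- recon_oracle(n, npos, sens = sens, spec = spec)
    expect_equal(nrow(got), nrow(oracle))
    expect_true(any(got$tp == tp & got$tn == tn))
  }
})

test_that("truncation explains the development column where half-up cannot", {
  # the joint development column (sens 0.54, spec 0.77, ppv 0.12, npv 0.96)
  # admits no matrix under half-up (candidate tn give npv ~0.965 -> 0.97)
  # but does under truncation
  expect_equal(nrow(reconstruct_confusion_matrix(422, 24, sens = 0.54,
                                                 spec = 0.77, ppv = 0.12,
                                                 npv = 0.96,
                                                 rounding = "half_up")),
               0)
  trunc <- reconstruct_confusion_matrix(422, 24, sens = 0.54, spec = 0.77,
                                        ppv = 0.12, npv = 0.96,
                                        rounding = "truncate")
  expect_gt(nrow(trunc), 0)
  expect_true(all(trunc$rounding == "truncate"))
  expect_true(all(trunc$tp == 13))
})
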