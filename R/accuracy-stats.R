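# Diagnostic-accuracy statistics: confusion matrices, Wilson score
# intervals, diagnostic summaries, ROC/AUC, Hanley-McNeil SE and the
# correlated-AUC z-test, and inversion of rounded published statistics.

# Confusion matrix ------------------------------------------------------------

#' Construct a confusion matrix from four counts
#'
#' @param tp,fp,fn,tn non-negative integer lesion counts.
#' @return object of class `confusion_matrix`.
#' @export
new_confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop("confusion-matrix cells must be non-negative integers")
  structure(as.list(setNames(as.integer(cells), names(cells))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Cross-tabulate scoring results against the reference standard
#'
#' Aligns a `score_result` with its `lesion_cohort` by `lesion_id` and
#' counts test-positive/-negative lesions against the chosen reference
#' definition: `"suspicious"` (the reference standard labelled the lesion
#' as warranting referral, excision or short-term monitoring) or
#' `"melanoma"` (reference diagnosis melanoma, optionally pooling lentigo
#' maligna).
#'
#' @param results a `score_result` data frame.
#' @param records the matching `lesion_cohort`.
#' @param positive reference definition, `"suspicious"` or `"melanoma"`.
#' @param include_lentigo_maligna for `positive = "melanoma"`, pool lentigo
#'   maligna with melanoma (default `TRUE`).
#' @param incomplete `"drop"` (default) silently drops lesions with `NA`
#'   classification (e.g. an unrecorded 7-point block); `"error"` fails.
#' @return a `confusion_matrix`.
#' @export
confusion_matrix <- function(results, records,
                             positive = c("suspicious", "melanoma"),
                             include_lentigo_maligna = TRUE,
                             incomplete = c("drop", "error")) {
  positive <- match.arg(positive)
  incomplete <- match.arg(incomplete)
  if (anyDuplicated(results$lesion_id) || anyDuplicated(records$lesion_id))
    stop("duplicate lesion_id")
  idx <- match(results$lesion_id, records$lesion_id)
  if (anyNA(idx)) stop("unmatched lesion_id: ",
                       paste(head(results$lesion_id[is.na(idx)], 5),
                             collapse = ", "))
  records <- records[idx, , drop = FALSE]
  ref <- if (positive == "suspicious") records$reference_suspicious
         else melanoma_positive(records, include_lentigo_maligna)
  test <- results$classification == "suspicious"
  if (anyNA(test)) {
    if (incomplete == "error") stop("NA classification in results")
    keep <- !is.na(test)
    test <- test[keep]; ref <- ref[keep]
  }
  new_confusion_matrix(tp = sum(test & ref), fp = sum(test & !ref),
                       fn = sum(!test & ref), tn = sum(!test & !ref))
}

# Wilson interval -------------------------------------------------------------

#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval has good coverage at small sample sizes and never
#' escapes `[0, 1]`: with `p = successes/trials` and normal quantile `z`,
#' the centre is `(p + z^2/2n) / (1 + z^2/n)` and the half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`.
#'
#' @param successes,trials non-negative integers, `successes <= trials`,
#'   `trials >= 1`.
#' @param confidence confidence level (default 0.95).
#' @param z_quantile optional explicit normal quantile; by default
#'   `qnorm((1 + confidence)/2)` (1.959964 at 95%).
#' @return object of class `proportion_ci` with fields `successes`,
#'   `trials`, `estimate`, `lower`, `upper`, `confidence`, `z_quantile`.
#' @export
#' @examples
#' wilson_interval(13, 24)
wilson_interval <- function(successes, trials, confidence = 0.95,
                            z_quantile = NULL) {
  if (length(trials) != 1 || is.na(trials) || trials < 1)
    stop("trials must be a single integer >= 1")
  if (is.na(successes) || successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]")
  z <- z_quantile %||% qnorm((1 + confidence) / 2)
  n <- trials
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  halfwidth <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # at the boundaries the score bound is exactly the estimate; avoid
  # floating-point residue of centre - halfwidth there
  lower <- if (successes == 0) 0 else max(0, centre - halfwidth)
  upper <- if (successes == trials) 1 else min(1, centre + halfwidth)
  structure(list(successes = as.integer(successes), trials = as.integer(n),
                 estimate = p,
                 lower = lower,
                 upper = upper,
                 confidence = confidence, z_quantile = z),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, digits = 2, ...) {
  cat(sprintf("%s/%s = %.*f (%.*f-%.*f) [%g%% Wilson]\n",
              x$successes, x$trials, digits, x$estimate, digits, x$lower,
              digits, x$upper, 100 * x$confidence))
  invisible(x)
}

# Diagnostic summary -----------------------------------------------------------

#' Sensitivity, specificity and predictive values with Wilson intervals
#'
#' Computes the four operating characteristics of a binary test from a
#' confusion matrix, each with a Wilson interval. A statistic whose
#' denominator is zero is returned as an explicit undefined marker
#' (`undefined = TRUE`, `NA` estimate), never as `NaN`.
#'
#' @param cm a `confusion_matrix`.
#' @param confidence confidence level for the intervals.
#' @param z_quantile optional explicit normal quantile (see
#'   [wilson_interval()]).
#' @return a `diagnostic_summary` data frame with one row per statistic
#'   (`sensitivity`, `specificity`, `ppv`, `npv`) and columns `successes`,
#'   `trials`, `estimate`, `lower`, `upper`, `undefined`.
#' @export
diagnostic_summary <- function(cm, confidence = 0.95, z_quantile = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  parts <- list(sensitivity = c(cm$tp, cm$tp + cm$fn),
                specificity = c(cm$tn, cm$fp + cm$tn),
                ppv = c(cm$tp, cm$tp + cm$fp),
                npv = c(cm$tn, cm$tn + cm$fn))
  rows <- lapply(names(parts), function(nm) {
    k <- parts[[nm]][1]; n <- parts[[nm]][2]
    if (n == 0)
      return(data.frame(statistic = nm, successes = k, trials = 0L,
                        estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, undefined = TRUE))
    ci <- wilson_interval(k, n, confidence, z_quantile)
    data.frame(statistic = nm, successes = k, trials = n,
               estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
               undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "confusion_matrix") <- cm
  attr(out, "confidence") <- confidence
  class(out) <- c("diagnostic_summary", "data.frame")
  out
}

#' @export
print.diagnostic_summary <- function(x, digits = 2, ...) {
  labels <- c(sensitivity = "Sensitivity",
              specificity = "Specificity",
              ppv = "Positive predictive value",
              npv = "Negative predictive value")
  cat(sprintf("Operating characteristics (%g%% CI, Wilson)\n",
              100 * attr(x, "confidence")))
  for (i in seq_len(nrow(x))) {
    if (x$undefined[i]) {
      cat(sprintf("  %-26s undefined (zero denominator)\n",
                  labels[[x$statistic[i]]]))
    } else {
      cat(sprintf("  %-26s %.*f (%.*f-%.*f)   [%d/%d]\n",
                  labels[[x$statistic[i]]], digits, x$estimate[i], digits,
                  x$lower[i], digits, x$upper[i], x$successes[i],
                  x$trials[i]))
    }
  }
  invisible(x)
}

# ROC -------------------------------------------------------------------------

#' Empirical ROC curve with trapezoidal AUC
#'
#' Higher scores are more suspicious. One operating point is produced per
#' distinct score value (classifying `score >= threshold` positive), plus
#' the endpoints (0,0) and (1,1); the AUC is the trapezoidal area, which
#' equals the Mann-Whitney pair-count statistic with ties counted one half.
#'
#' Lesions removed by a classification gate carry no score; two policies
#' are offered: `"exclude"` drops them from the curve (the analysis used
#' when the gate is treated as a separate triage step), `"floor"` assigns
#' them a score strictly below the observed minimum (a
#' classification-consistent view in which gated lesions are the least
#' suspicious).
#'
#' @param scores numeric scores (`NA` allowed only for gated lesions).
#' @param labels logical (or 0/1) reference-positive indicators.
#' @param gated optional logical vector marking gated lesions.
#' @param gated_policy `"exclude"` or `"floor"`.
#' @return object of class `roc_curve`: `thresholds` (descending),
#'   `points` (data frame `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, gated = NULL,
                      gated_policy = c("exclude", "floor")) {
  gated_policy <- match.arg(gated_policy)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  gated <- gated %||% rep(FALSE, length(scores))
  if (any(is.na(scores) & !gated))
    stop("NA score for ungated lesion")
  if (gated_policy == "exclude") {
    keep <- !gated
    scores <- scores[keep]; labels <- labels[keep]
  } else {
    if (all(gated)) stop("all lesions gated")
    scores[gated] <- min(scores[!gated]) - 1
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative after gating policy")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thresholds, function(t) sum(labels & scores == t),
                      numeric(1)))
  fp <- cumsum(vapply(thresholds, function(t) sum(!labels & scores == t),
                      numeric(1)))
  # trapezoid on cumulative counts; numerator is exact in half-integers so
  # the AUC agrees with the pairwise Mann-Whitney count to machine identity
  num <- sum(diff(c(0, fp)) * (c(0, head(tp, -1)) + tp) / 2)
  points <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(thresholds = thresholds, points = points,
                 auc = num / (n_pos * n_neg),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d positives, %d negatives, %d thresholds, AUC %.4f\n",
              x$n_pos, x$n_neg, length(x$thresholds), x$auc))
  invisible(x)
}

# Hanley-McNeil ---------------------------------------------------------------

#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form standard error of a trapezoidal/Mann-Whitney AUC `A` from
#' `n_pos` positive and `n_neg` negative cases:
#' `SE = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos * n_neg))` with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc AUC in `[0, 1]`.
#' @param n_pos,n_neg numbers of positive and negative cases (`>= 1`).
#' @return the standard error.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  if (any(auc < 0 | auc > 1)) stop("auc must lie in [0, 1]")
  if (any(n_pos < 1) || any(n_neg < 1)) stop("n_pos and n_neg must be >= 1")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(pmax(v, 0))
}

#' Normal-approximation confidence interval for an AUC
#'
#' `auc +/- z * SE` with the Hanley-McNeil standard error, clamped to
#' `[0, 1]`.
#'
#' @inheritParams hanley_mcneil_se
#' @param confidence confidence level.
#' @return named numeric `c(lower, upper)`.
#' @export
hanley_mcneil_ci <- function(auc, n_pos, n_neg, confidence = 0.95) {
  z <- qnorm((1 + confidence) / 2)
  se <- hanley_mcneil_se(auc, n_pos, n_neg)
  c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
}

#' Correlation surrogate for paired AUC comparison
#'
#' The correlated-AUC z-test needs the correlation `r` induced between two
#' AUCs measured on the same cases. The original manual method reads `r`
#' off a published lookup table indexed by the average within-class score
#' correlation and the average AUC; the standard working surrogate
#' implemented here is the mean of the Pearson correlations of the two
#' score vectors within the positives and within the negatives.
#'
#' @param scores1,scores2 paired numeric score vectors.
#' @param labels logical reference-positive indicators.
#' @return correlation estimate in `[-1, 1]`.
#' @export
paired_auc_correlation <- function(scores1, scores2, labels) {
  labels <- as.logical(labels)
  comps <- c(
    if (sum(labels) >= 2) cor(scores1[labels], scores2[labels]),
    if (sum(!labels) >= 2) cor(scores1[!labels], scores2[!labels]))
  comps <- comps[!is.na(comps)]
  if (length(comps) == 0)
    stop("cannot estimate paired-score correlation (degenerate scores)")
  mean(comps)
}

#' z-test for two correlated AUCs
#'
#' Compares two AUCs measured on the same cases:
#' `z = (auc1 - auc2) / sqrt(se1^2 + se2^2 - 2 r se1 se2)` with a two-sided
#' normal p-value. Equal AUCs give `z = 0`, `p = 1`; with `r = 0` the test
#' reduces to the unpaired two-standard-error z-test.
#'
#' @param auc1,auc2 the two AUCs.
#' @param se1,se2 their standard errors (e.g. [hanley_mcneil_se()]).
#' @param r correlation between the two AUC estimates, supplied directly or
#'   via [paired_auc_correlation()].
#' @return object of class `auc_comparison` with fields `auc1`, `auc2`,
#'   `se1`, `se2`, `r`, `z_statistic`, `p_value`.
#' @export
compare_correlated_auc <- function(auc1, auc2, se1, se2, r) {
  if (abs(r) > 1) stop("r must lie in [-1, 1]")
  if (auc1 == auc2) {
    z <- 0
  } else {
    v <- se1^2 + se2^2 - 2 * r * se1 * se2
    if (v <= 0)
      stop("non-positive variance of the AUC difference ",
           "(r too large for the given standard errors)")
    z <- (auc1 - auc2) / sqrt(v)
  }
  structure(list(auc1 = auc1, auc2 = auc2, se1 = se1, se2 = se2, r = r,
                 z_statistic = z, p_value = 2 * pnorm(-abs(z))),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("Correlated AUC comparison: %.3f vs %.3f (r = %.3f)\n",
              x$auc1, x$auc2, x$r))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$z_statistic, x$p_value))
  invisible(x)
}

#' Compare two scoring rules' AUCs on the same lesions
#'
#' Computes both empirical AUCs with [roc_curve()], their Hanley-McNeil
#' standard errors, the paired correlation surrogate, and the correlated
#' z-test.
#'
#' @param scores1,scores2 paired score vectors (same lesions, same order).
#' @param labels logical reference-positive indicators.
#' @param confidence confidence level for the attached AUC intervals.
#' @return an `auc_comparison` with additional fields `ci1`, `ci2`,
#'   `n_pos`, `n_neg`.
#' @export
compare_auc_paired <- function(scores1, scores2, labels, confidence = 0.95) {
  roc1 <- roc_curve(scores1, labels)
  roc2 <- roc_curve(scores2, labels)
  se1 <- hanley_mcneil_se(roc1$auc, roc1$n_pos, roc1$n_neg)
  se2 <- hanley_mcneil_se(roc2$auc, roc2$n_pos, roc2$n_neg)
  r <- paired_auc_correlation(scores1, scores2, labels)
  out <- compare_correlated_auc(roc1$auc, roc2$auc, se1, se2, r)
  out$ci1 <- hanley_mcneil_ci(roc1$auc, roc1$n_pos, roc1$n_neg, confidence)
  out$ci2 <- hanley_mcneil_ci(roc2$auc, roc2$n_pos, roc2$n_neg, confidence)
  out$n_pos <- roc1$n_pos
  out$n_neg <- roc1$n_neg
  out
}

# Reconstruction of rounded published statistics -------------------------------

.round_rule <- function(x, rule, digits = 2) {
  m <- 10^digits
  # 1e-9 guards against doubles sitting epsilon below a .xx5 boundary
  switch(rule,
         half_up = floor(x * m + 0.5 + 1e-9) / m,
         half_even = round(x, digits),
         truncate = floor(x * m + 1e-9) / m,
         stop("unknown rounding rule: ", rule))
}

#' Invert rounded published accuracy statistics to confusion matrices
#'
#' Published diagnostic-accuracy tables print sensitivity, specificity and
#' predictive values rounded to two decimals; the underlying integer
#' confusion matrix is rarely given. Given the total number of lesions, the
#' number of reference positives, and any subset of the four printed
#' statistics, this enumerates all `tp` in `[0, n_positive]` and `tn` in
#' `[0, n_total - n_positive]` and returns every matrix whose recomputed
#' statistics reproduce the printed values under the rounding rule(s). An
#' empty result is a valid, reportable outcome: it proves the printed
#' statistics are mutually inconsistent with the stated denominators.
#'
#' @param n_total total lesions; `n_positive` reference positives.
#' @param n_positive number of reference-positive lesions.
#' @param sens,spec,ppv,npv printed values (2 dp) or `NA` to leave
#'   unconstrained.
#' @param rounding character vector of rules to try: any of `"half_up"`,
#'   `"half_even"`, `"truncate"`. Each returned row records the rule it
#'   satisfies.
#' @param digits decimals of the printed values (default 2).
#' @return data frame with columns `tp`, `fp`, `fn`, `tn`, `rounding`
#'   (zero rows when no matrix is consistent).
#' @export
reconstruct_confusion_matrix <- function(n_total, n_positive,
                                         sens = NA, spec = NA,
                                         ppv = NA, npv = NA,
                                         rounding = "half_up", digits = 2) {
  stopifnot(n_positive >= 0, n_positive <= n_total)
  n_neg <- n_total - n_positive
  tp <- rep(0:n_positive, each = n_neg + 1)
  tn <- rep(0:n_neg, times = n_positive + 1)
  fn <- n_positive - tp
  fp <- n_neg - tn
  m <- 10^digits
  out <- list()
  for (rule in rounding) {
    ok <- rep(TRUE, length(tp))
    chk <- function(ok, num, den, target) {
      if (is.na(target)) return(ok)
      val <- .round_rule(ifelse(den > 0, num / den, NA_real_), rule, digits)
      ok & !is.na(val) & round(val * m) == round(target * m)
    }
    ok <- chk(ok, tp, rep(n_positive, length(tp)), sens)
    ok <- chk(ok, tn, rep(n_neg, length(tp)), spec)
    ok <- chk(ok, tp, tp + fp, ppv)
    ok <- chk(ok, tn, tn + fn, npv)
    if (any(ok))
      out[[rule]] <- data.frame(tp = tp[ok], fp = fp[ok], fn = fn[ok],
                                tn = tn[ok], rounding = rule,
                                stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(tp = integer(), fp = integer(), fn = integer(),
                      tn = integer(), rounding = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
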