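# Seeded generator of expert-scored lesion cohorts emulating primary-care
# case mix, with two calibration knobs tying the melanoma-associated
# feature rates to published operating characteristics.

# the five features whose rates the calibration knobs scale
.melanoma_features <- c("dermal_melanin", "collagen_holes",
                        "erythematous_blush", "blood_displacement",
                        "blood_vessels")

#' Construct a cohort-simulation configuration
#'
#' Defines the generative model for a synthetic lesion cohort: the
#' diagnosis mix, per-diagnosis Bernoulli feature profiles (features are
#' conditionally independent given diagnosis — a documented modelling
#' simplification), the probability that the reference standard labels each
#' diagnosis suspicious, log-normal lesion diameters, normal patient ages,
#' and a mandatory seed. Two scalar knobs, `suspicious_feature_rate` and
#' `benign_feature_rate`, multiply the melanoma-associated feature
#' probabilities (dermal melanin, collagen holes, erythematous blush, blood
#' displacement, blood vessels) of reference-suspicious and
#' reference-benign lesions respectively (clamped to `[0, 1]`); they are
#' the free parameters adjusted by [calibrate_profiles()].
#'
#' @param name config name (used in lesion ids).
#' @param n_lesions default cohort size.
#' @param prevalence named non-negative vector over diagnoses; counts are
#'   accepted and normalised to probabilities (original values kept as the
#'   `"counts"` attribute).
#' @param feature_profiles named list: `default` plus per-diagnosis
#'   overrides, each a named vector of Bernoulli probabilities over the
#'   eight SIAscopic features and seven checklist items.
#' @param suspicious_given_diagnosis named vector of probabilities that the
#'   reference standard labels a lesion of each diagnosis suspicious
#'   (missing diagnoses default to 0).
#' @param diameter_distribution named list: `default` plus per-diagnosis
#'   overrides, each `list(meanlog, sdlog)` of the diameter (mm) log-normal.
#' @param age_distribution `list(mean, sd, min)` of patient age in years.
#' @param seed integer seed (mandatory).
#' @param suspicious_feature_rate,benign_feature_rate calibration knobs
#'   (default 1: profiles used as given).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(name, n_lesions, prevalence, feature_profiles,
                          suspicious_given_diagnosis,
                          diameter_distribution, age_distribution, seed,
                          suspicious_feature_rate = 1,
                          benign_feature_rate = 1) {
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  prevalence <- unlist(prevalence)
  bad <- setdiff(names(prevalence), diagnosis_levels)
  if (length(bad) > 0) stop("unknown diagnosis in prevalence: ",
                            paste(bad, collapse = ", "))
  if (any(prevalence < 0) || sum(prevalence) <= 0)
    stop("prevalence must be non-negative with positive sum")
  counts <- prevalence
  prev <- setNames(rep(0, length(diagnosis_levels)), diagnosis_levels)
  prev[names(prevalence)] <- prevalence / sum(prevalence)
  stopifnot(abs(sum(prev) - 1) < 1e-9)

  all_fields <- c(sia_features, seven_point_items)
  base <- setNames(rep(0, length(all_fields)), all_fields)
  default_profile <- base
  if (!is.null(feature_profiles$default)) {
    d <- unlist(feature_profiles$default)
    default_profile[names(d)] <- d
  }
  profiles <- matrix(rep(default_profile, each = length(diagnosis_levels)),
                     nrow = length(diagnosis_levels),
                     dimnames = list(diagnosis_levels, all_fields))
  for (dx in intersect(names(feature_profiles), diagnosis_levels)) {
    ov <- unlist(feature_profiles[[dx]])
    bad <- setdiff(names(ov), all_fields)
    if (length(bad) > 0) stop("unknown feature in profile for ", dx, ": ",
                              paste(bad, collapse = ", "))
    profiles[dx, names(ov)] <- ov
  }
  if (any(profiles < 0) || any(profiles > 1))
    stop("feature probabilities must lie in [0, 1]")

  sgd <- setNames(rep(0, length(diagnosis_levels)), diagnosis_levels)
  s <- unlist(suspicious_given_diagnosis)
  bad <- setdiff(names(s), diagnosis_levels)
  if (length(bad) > 0) stop("unknown diagnosis in suspicious_given_diagnosis: ",
                            paste(bad, collapse = ", "))
  sgd[names(s)] <- s
  if (any(sgd < 0) || any(sgd > 1)) stop("probabilities must lie in [0, 1]")

  dd_default <- diameter_distribution$default %||% list(meanlog = 1.5,
                                                        sdlog = 0.45)
  diam <- lapply(setNames(diagnosis_levels, diagnosis_levels), function(dx)
    diameter_distribution[[dx]] %||% dd_default)

  age <- list(mean = age_distribution$mean %||% 48,
              sd = age_distribution$sd %||% 15,
              min = age_distribution$min %||% 18)
  if (suspicious_feature_rate < 0 || benign_feature_rate < 0)
    stop("feature-rate knobs must be non-negative")

  structure(list(name = name, n_lesions = as.integer(n_lesions),
                 prevalence = prev, feature_profiles = profiles,
                 suspicious_given_diagnosis = sgd,
                 diameter_distribution = diam, age_distribution = age,
                 seed = as.integer(seed),
                 suspicious_feature_rate = suspicious_feature_rate,
                 benign_feature_rate = benign_feature_rate),
            counts = counts,
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$name, "- n =", x$n_lesions, ", seed =", x$seed,
      "\n")
  nz <- x$prevalence[x$prevalence > 0]
  cat("  prevalence:", paste(names(nz), sprintf("%.3f", nz), sep = "=",
                             collapse = ", "), "\n")
  cat(sprintf("  feature-rate knobs: suspicious %.4g, benign %.4g\n",
              x$suspicious_feature_rate, x$benign_feature_rate))
  invisible(x)
}

#' Load a cohort configuration from YAML
#'
#' @param path YAML file with the fields of [cohort_config()].
#' @return a `cohort_config`.
#' @export
load_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_config(name = y$name, n_lesions = y$n_lesions,
                prevalence = y$prevalence,
                feature_profiles = y$feature_profiles,
                suspicious_given_diagnosis = y$suspicious_given_diagnosis,
                diameter_distribution = y$diameter_distribution,
                age_distribution = y$age_distribution,
                seed = y$seed,
                suspicious_feature_rate = y$suspicious_feature_rate %||% 1,
                benign_feature_rate = y$benign_feature_rate %||% 1)
}

#' Shipped cohort configurations
#'
#' Three configs transcribed from the study populations' diagnosis counts:
#' `"uk_development"` (n = 422), `"uk_validation"` (n = 208) and
#' `"australian_2009"` (n = 581). Per-diagnosis suspicious probabilities
#' are free parameters chosen so the expected number of suspicious lesions
#' matches the reported 24, 6 and 52 respectively.
#'
#' @param name config name.
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(name = c("australian_2009",
                                           "uk_development",
                                           "uk_validation")) {
  name <- match.arg(name)
  load_cohort_config(system.file("extdata", "configs",
                                 paste0(name, ".yaml"),
                                 package = "siascore", mustWork = TRUE))
}

# Simulation ------------------------------------------------------------------

.effective_profile <- function(config, dx, suspicious) {
  p <- config$feature_profiles[dx, , drop = TRUE]
  rate <- if (suspicious) config$suspicious_feature_rate
          else config$benign_feature_rate
  p[.melanoma_features] <- pmin(1, rate * p[.melanoma_features])
  p
}

#' Simulate an expert-scored lesion cohort
#'
#' Draws `n` lesions: diagnosis from the prevalence vector; the
#' reference-suspicious label per `suspicious_given_diagnosis`; diameter
#' from the per-diagnosis log-normal, rounded to 0.1 mm; integer age
#' (normal, truncated below at the configured minimum); each feature
#' independently Bernoulli from the diagnosis profile, with the
#' melanoma-associated features scaled by the calibration knob matching the
#' lesion's suspicious status. Reference tier is `histopathology` for
#' melanoma, lentigo maligna and basal cell carcinoma, `in_person_expert`
#' for other suspicious lesions, `image_expert` otherwise. All randomness
#' flows from the single seed.
#'
#' @param config a `cohort_config`.
#' @param n number of lesions (default `config$n_lesions`).
#' @param seed seed (default `config$seed`).
#' @param dataset_tag tag recorded on the records.
#' @return a validated `lesion_cohort` with `n` rows.
#' @export
simulate_cohort <- function(config, n = config$n_lesions,
                            seed = config$seed, dataset_tag = "other") {
  stopifnot(inherits(config, "cohort_config"), n >= 0)
  set.seed(seed)
  dx <- sample(diagnosis_levels, n, replace = TRUE, prob = config$prevalence)
  suspicious <- runif(n) < config$suspicious_given_diagnosis[dx]
  meanlog <- vapply(config$diameter_distribution[dx], `[[`, 0, "meanlog")
  sdlog <- vapply(config$diameter_distribution[dx], `[[`, 0, "sdlog")
  diameter <- pmax(0.1, round(rlnorm(n, meanlog, sdlog), 1))
  age <- pmax(config$age_distribution$min,
              as.integer(round(rnorm(n, config$age_distribution$mean,
                                     config$age_distribution$sd))))
  sex <- sample(c("male", "female"), n, replace = TRUE)

  all_fields <- c(sia_features, seven_point_items)
  feat <- matrix(NA, nrow = n, ncol = length(all_fields),
                 dimnames = list(NULL, all_fields))
  rate <- ifelse(suspicious, config$suspicious_feature_rate,
                 config$benign_feature_rate)
  for (f in all_fields) {
    p <- config$feature_profiles[dx, f]
    if (f %in% .melanoma_features) p <- pmin(1, rate * p)
    feat[, f] <- runif(n) < p
  }

  tier <- ifelse(dx %in% c("melanoma", "lentigo_maligna",
                           "basal_cell_carcinoma"), "histopathology",
                 ifelse(suspicious, "in_person_expert", "image_expert"))
  out <- data.frame(
    lesion_id = sprintf("%s-%06d", config$name, seq_len(n)),
    dataset_tag = rep(dataset_tag, n),
    as.data.frame(feat)[sia_features],
    as.data.frame(feat)[seven_point_items],
    diameter_mm = diameter,
    diameter_gt_6mm = diameter > 6,
    age_years = age,
    age_band = ifelse(age >= 50, ">=50", "<50"),
    sex = sex,
    reference_diagnosis = dx,
    reference_tier = tier,
    reference_suspicious = suspicious,
    stringsAsFactors = FALSE)
  if (n == 0) {
    out <- out[0, , drop = FALSE]
    class(out) <- c("lesion_cohort", "data.frame")
    return(out)
  }
  validate_lesions(out)
}

# Expected operating characteristics ------------------------------------------

# P(sum of independent Bernoulli(p_i) * w_i >= threshold), by convolution
.score_ge_prob <- function(p, w, threshold) {
  maxs <- sum(w)
  if (threshold > maxs) return(0)
  d <- c(1, rep(0, maxs))
  for (i in seq_along(p)) {
    if (w[i] == 0 || p[i] == 0) next
    shifted <- c(rep(0, w[i]), head(d, maxs + 1 - w[i]))
    d <- d * (1 - p[i]) + shifted * p[i]
  }
  sum(d[(threshold + 1):(maxs + 1)])
}

.test_positive_prob <- function(config, dx, suspicious, algorithm) {
  prof <- .effective_profile(config, dx, suspicious)
  keep <- 1
  if (algorithm$gate)
    keep <- (1 - prof[["blood_lacunes"]]) *
      (1 - prof[["collagen_white_dots"]]) *
      (1 - prof[["cerebriform_melanin"]])
  w <- algorithm$weights
  p <- numeric(length(w))
  for (i in seq_along(w)) {
    key <- names(w)[i]
    p[i] <- switch(key,
      # diameters are generated at 0.1 mm precision, so "rounded value
      # strictly greater than the cut" means the latent diameter >= cut+0.05
      size_term = 1 - plnorm(algorithm$size_threshold_mm + 0.05,
                             config$diameter_distribution[[dx]]$meanlog,
                             config$diameter_distribution[[dx]]$sdlog),
      # integer ages: round(Y) >= edge  <=>  Y >= edge - 0.5
      age_term = 1 - pnorm(algorithm$age_band_edge_years - 0.5,
                           config$age_distribution$mean,
                           config$age_distribution$sd),
      prof[[key]])
  }
  keep * .score_ge_prob(p, as.numeric(w), algorithm$suspicious_threshold)
}

#' Exact expected sensitivity and specificity under a cohort config
#'
#' Computes, in closed form (enumeration over the score distribution of the
#' independent Bernoulli features plus size and age terms, within each
#' diagnosis-by-suspicious stratum), the expected sensitivity and
#' specificity of a scoring rule for the 'suspicious' reference label on
#' cohorts generated from `config`. This is the deterministic counterpart
#' of simulating a very large cohort and scoring it, and is the default
#' objective of [calibrate_profiles()].
#'
#' @param config a `cohort_config`.
#' @param algorithm a `weight_config` (default: shipped PCSA).
#' @return list with `sensitivity` and `specificity`.
#' @export
expected_operating_characteristics <- function(config,
                                               algorithm = default_config("pcsa")) {
  prev <- config$prevalence
  sgd <- config$suspicious_given_diagnosis
  num_s <- num_b <- den_s <- den_b <- 0
  for (dx in diagnosis_levels) {
    if (prev[[dx]] == 0) next
    if (sgd[[dx]] > 0) {
      pp <- .test_positive_prob(config, dx, TRUE, algorithm)
      num_s <- num_s + prev[[dx]] * sgd[[dx]] * pp
      den_s <- den_s + prev[[dx]] * sgd[[dx]]
    }
    if (sgd[[dx]] < 1) {
      pp <- .test_positive_prob(config, dx, FALSE, algorithm)
      num_b <- num_b + prev[[dx]] * (1 - sgd[[dx]]) * pp
      den_b <- den_b + prev[[dx]] * (1 - sgd[[dx]])
    }
  }
  list(sensitivity = if (den_s > 0) num_s / den_s else NA_real_,
       specificity = if (den_b > 0) 1 - num_b / den_b else NA_real_)
}

# Calibration -----------------------------------------------------------------

.bisect_rate <- function(f, target, increasing, tolerance, max_iter,
                         hi_cap = 64) {
  trace <- list()
  note <- function(iter, rate, value)
    trace[[length(trace) + 1L]] <<- data.frame(iteration = iter, rate = rate,
                                               value = value)
  lo <- 0; f_lo <- f(lo); note(0L, lo, f_lo)
  hi <- 1; f_hi <- f(hi); note(0L, hi, f_hi)
  # the objective saturates once all clamped probabilities hit 1, so stop
  # expanding the bracket when the target is reached up to tolerance
  reaches <- function(v) if (increasing) v >= target - tolerance
                         else v <= target + tolerance
  it <- 0L
  while (!reaches(f_hi) && hi < hi_cap) {
    hi <- hi * 2; f_hi <- f(hi); note(it, hi, f_hi)
  }
  best <- if (abs(f_hi - target) < abs(f_lo - target))
    c(hi, f_hi) else c(lo, f_lo)
  while (it < max_iter && abs(best[2] - target) > tolerance) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    note(it, mid, f_mid)
    if (abs(f_mid - target) < abs(best[2] - target)) best <- c(mid, f_mid)
    if (xor(f_mid < target, !increasing)) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  converged <- abs(best[2] - target) <= tolerance
  if (!converged)
    warning("calibration target ", signif(target, 4),
            " not reached within tolerance; best value ",
            signif(best[2], 4), " at rate ", signif(best[1], 4))
  list(rate = best[1], value = best[2], converged = converged,
       trace = do.call(rbind, trace))
}

#' Calibrate cohort feature rates to target operating characteristics
#'
#' Adjusts the two free scalar knobs of a `cohort_config` — the rate at
#' which melanoma-associated features appear in reference-suspicious
#' lesions (`suspicious_feature_rate`, driving sensitivity) and their
#' background rate in reference-benign lesions (`benign_feature_rate`,
#' driving specificity) — by bisection until the scoring rule's sensitivity
#' and specificity match the targets within `tolerance`. Because the
#' suspicious label is drawn independently of the knobs, the two bisections
#' are separable: sensitivity is monotone increasing in the first knob and
#' specificity monotone decreasing in the second.
#'
#' Two objective estimators are offered. `"analytic"` (default) bisects the
#' exact expected operating characteristics from
#' [expected_operating_characteristics()], which is free of Monte-Carlo
#' error. `"empirical"` draws a single common-random-numbers cohort of
#' `n_calibration` lesions from `config$seed` and re-thresholds the same
#' uniform draws at each candidate rate, so the empirical objective is also
#' deterministic and monotone in the knob.
#'
#' @param config a `cohort_config`.
#' @param target_sensitivity,target_specificity point-estimate targets for
#'   the 'suspicious' classification.
#' @param algorithm the scoring rule to calibrate against (default PCSA).
#' @param n_calibration cohort size for the empirical estimator.
#' @param tolerance acceptable absolute deviation of each statistic.
#' @param max_iter bisection iteration budget per knob; on non-convergence
#'   a warning reports the best value found.
#' @param estimator `"analytic"` or `"empirical"`.
#' @return the updated `cohort_config`, with attributes
#'   `"calibration_trace"` (data frame of all evaluations) and
#'   `"calibration_achieved"` (list of achieved sensitivity/specificity and
#'   convergence flags).
#' @export
calibrate_profiles <- function(config, target_sensitivity,
                               target_specificity,
                               algorithm = default_config("pcsa"),
                               n_calibration = 5000, tolerance = 0.005,
                               max_iter = 60,
                               estimator = c("analytic", "empirical")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(config, "cohort_config"))
  if (estimator == "analytic") {
    sens_fun <- function(rate) {
      cfg <- config; cfg$suspicious_feature_rate <- rate
      expected_operating_characteristics(cfg, algorithm)$sensitivity
    }
    spec_fun <- function(rate) {
      cfg <- config; cfg$benign_feature_rate <- rate
      expected_operating_characteristics(cfg, algorithm)$specificity
    }
  } else {
    skel <- .calibration_skeleton(config, n_calibration)
    sens_fun <- function(rate)
      .empirical_oc(skel, config, algorithm, rate_s = rate)$sensitivity
    spec_fun <- function(rate)
      .empirical_oc(skel, config, algorithm, rate_b = rate)$specificity
  }
  cal_s <- .bisect_rate(sens_fun, target_sensitivity, increasing = TRUE,
                        tolerance = tolerance, max_iter = max_iter)
  cal_b <- .bisect_rate(spec_fun, target_specificity, increasing = FALSE,
                        tolerance = tolerance, max_iter = max_iter)
  config$suspicious_feature_rate <- cal_s$rate
  config$benign_feature_rate <- cal_b$rate
  trace <- rbind(cbind(knob = "suspicious_feature_rate", cal_s$trace),
                 cbind(knob = "benign_feature_rate", cal_b$trace))
  attr(config, "calibration_trace") <- trace
  attr(config, "calibration_achieved") <- list(
    sensitivity = cal_s$value, specificity = cal_b$value,
    converged = cal_s$converged && cal_b$converged,
    estimator = estimator)
  config
}

# draw everything except the melanoma-associated features once; keep the
# uniforms so candidate rates re-threshold the same draws (common random
# numbers: the empirical objective is deterministic and monotone in the knob)
.calibration_skeleton <- function(config, n) {
  base <- config
  base$suspicious_feature_rate <- 0
  base$benign_feature_rate <- 0
  records <- simulate_cohort(base, n = n, seed = config$seed)
  set.seed(config$seed + 1L)
  u <- matrix(runif(n * length(.melanoma_features)), nrow = n,
              dimnames = list(NULL, .melanoma_features))
  list(records = records, u = u)
}

.empirical_oc <- function(skel, config, algorithm, rate_s = NULL,
                          rate_b = NULL) {
  records <- skel$records
  rate <- ifelse(records$reference_suspicious,
                 rate_s %||% config$suspicious_feature_rate,
                 rate_b %||% config$benign_feature_rate)
  dx <- records$reference_diagnosis
  for (f in .melanoma_features)
    records[[f]] <- skel$u[, f] < pmin(1, rate * config$feature_profiles[dx, f])
  res <- score_lesions(records, algorithm$algorithm, algorithm)
  cm <- confusion_matrix(res, records, positive = "suspicious")
  list(sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$fp + cm$tn))
}
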