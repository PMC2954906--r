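# Independent oracles and record generators used across the suite. These
# deliberately avoid the package's own code paths wherever they check one.

# brute-force Mann-Whitney pair count (ties count one half)
mw_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  sum(cmp) / (length(pos) * length(neg))
}

# independent indicator-vector dot product for the SIAscopic rules
dot_score <- function(records, weights, size_threshold = 6, age_edge = 50) {
  vapply(seq_len(nrow(records)), function(i) {
    s <- 0
    for (key in names(weights)) {
      present <- switch(key,
        size_term = records$diameter_mm[i] > size_threshold,
        age_term = records$age_years[i] >= age_edge,
        records[[key]][i])
      s <- s + as.integer(present) * weights[[key]]
    }
    s
  }, numeric(1))
}

# random, fully explicit lesion records built without simulate_cohort
random_records <- function(n, seed, p_feature = 0.3, with_seven_point = TRUE) {
  set.seed(seed)
  out <- data.frame(lesion_id = sprintf("r%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (f in sia_features) out[[f]] <- runif(n) < p_feature
  if (with_seven_point)
    for (f in seven_point_items) out[[f]] <- runif(n) < p_feature
  out$diameter_mm <- round(runif(n, 1, 15), 1)
  out$diameter_gt_6mm <- out$diameter_mm > 6
  out$age_years <- sample(18:90, n, replace = TRUE)
  out$sex <- sample(c("male", "female"), n, replace = TRUE)
  out$reference_diagnosis <- sample(diagnosis_levels, n, replace = TRUE)
  out$reference_tier <- sample(reference_tiers, n, replace = TRUE)
  out$reference_suspicious <- runif(n) < 0.2
  validate_lesions(out)
}

# a minimal raw (all-character) CSV row for ingest tests
raw_row <- function(...) {
  row <- list(lesion_id = "L1", dermal_melanin = "0", collagen_holes = "0",
              erythematous_blush = "0", blood_displacement = "0",
              blood_vessels = "0", collagen_white_dots = "0",
              cerebriform_melanin = "0", blood_lacunes = "0",
              diameter_mm = "4.5", age_years = "35", sex = "female",
              reference_diagnosis = "naevus",
              reference_tier = "image_expert", reference_suspicious = "no")
  mods <- list(...)
  row[names(mods)] <- mods
  as.data.frame(row, stringsAsFactors = FALSE)
}

# brute-force reconstruction oracle: plain double loop, scalar arithmetic
recon_oracle <- function(n_total, n_positive, sens = NA, spec = NA,
                         ppv = NA, npv = NA) {
  r2 <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100
  hits <- list()
  for (tp in 0:n_positive) for (tn in 0:(n_total - n_positive)) {
    fn <- n_positive - tp
    fp <- n_total - n_positive - tn
    ok <- TRUE
    if (!is.na(sens)) ok <- ok && r2(tp / n_positive) == sens
    if (!is.na(spec)) ok <- ok && r2(tn / (fp + tn)) == spec
    if (!is.na(ppv)) ok <- ok && (tp + fp) > 0 && r2(tp / (tp + fp)) == ppv
    if (!is.na(npv)) ok <- ok && (tn + fn) > 0 && r2(tn / (tn + fn)) == npv
    if (ok) hits[[length(hits) + 1]] <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

# tiny cohort config with disjoint feature support between suspicious and
# benign lesions, used for calibration limit tests
toy_disjoint_config <- function(seed = 7) {
  cohort_config(
    name = "toy", n_lesions = 400,
    prevalence = c(naevus = 0.7, melanoma = 0.3),
    feature_profiles = list(
      default = c(dermal_melanin = 0, collagen_holes = 0,
                  erythematous_blush = 0, blood_displacement = 0,
                  blood_vessels = 0),
      melanoma = c(dermal_melanin = 1, collagen_holes = 1,
                   erythematous_blush = 1, blood_displacement = 1,
                   blood_vessels = 1)),
    suspicious_given_diagnosis = c(melanoma = 1, naevus = 0),
    diameter_distribution = list(default = list(meanlog = 1.2, sdlog = 0.3)),
    age_distribution = list(mean = 40, sd = 10, min = 18),
    seed = seed)
}
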