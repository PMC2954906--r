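# Rule-based diagnostic scoring: Moncrieff scoring system (MSS), Primary
# Care Scoring Algorithm (PCSA), and the 7-point melanoma checklist. All
# point values and thresholds live in config files, never in code.

#' Construct a scoring weight configuration
#'
#' A weight config fully determines one scoring rule: integer points per
#' feature (plus the derived `size_term` and `age_term` indicators for the
#' SIAscopic rules), the suspicious threshold, and the size/age cut points.
#'
#' @param algorithm rule name, e.g. `"pcsa"`, `"mss"`, `"seven_point"`.
#' @param weights named list/vector of non-negative integer points. For
#'   SIAscopic rules names must be SIAscopic features or `size_term` /
#'   `age_term`; for the checklist, 7-point item names.
#' @param suspicious_threshold integer `>= 1`; score at or above it
#'   classifies the lesion suspicious.
#' @param size_threshold_mm lesion-diameter cut in millimetres for the
#'   `size_term` point (default 6: "larger than 6 mm").
#' @param age_band_edge_years patient-age cut in years for the `age_term`
#'   point (default 50).
#' @param gate should the non-melanocytic gate (haemangioma / seborrhoeic
#'   keratosis) be applied before scoring? `TRUE` for the PCSA.
#' @return an object of class `weight_config`.
#' @export
weight_config <- function(algorithm, weights, suspicious_threshold,
                          size_threshold_mm = 6, age_band_edge_years = 50,
                          gate = identical(algorithm, "pcsa")) {
  weights <- unlist(weights)
  allowed <- if (identical(algorithm, "seven_point")) seven_point_items
             else c(sia_features, "size_term", "age_term")
  bad <- setdiff(names(weights), allowed)
  if (length(bad) > 0)
    stop("unknown weight key(s): ", paste(bad, collapse = ", "))
  if (any(weights < 0) || any(weights != floor(weights)))
    stop("weights must be non-negative integers")
  suspicious_threshold <- as.integer(suspicious_threshold)
  if (is.na(suspicious_threshold) || suspicious_threshold < 1)
    stop("suspicious_threshold must be an integer >= 1")
  structure(list(algorithm = algorithm,
                 weights = setNames(as.integer(weights), names(weights)),
                 suspicious_threshold = suspicious_threshold,
                 size_threshold_mm = size_threshold_mm,
                 age_band_edge_years = as.integer(age_band_edge_years),
                 gate = isTRUE(gate)),
            class = "weight_config")
}

#' @export
print.weight_config <- function(x, ...) {
  cat("<weight_config>", x$algorithm,
      if (x$gate) "(non-melanocytic gate applied)" else "", "\n")
  cat("  weights:", paste(names(x$weights), x$weights, sep = "=",
                          collapse = ", "), "\n")
  cat("  suspicious at score >=", x$suspicious_threshold, "\n")
  if (!identical(x$algorithm, "seven_point"))
    cat("  size term: diameter >", x$size_threshold_mm,
        "mm; age term: age >=", x$age_band_edge_years, "years\n")
  invisible(x)
}

#' Load a weight configuration from YAML
#'
#' @param path path to a YAML file with keys `algorithm`, `weights`,
#'   `suspicious_threshold` and optionally `size_threshold_mm`,
#'   `age_band_edge_years`, `gate`.
#' @return a `weight_config`.
#' @export
load_weight_config <- function(path) {
  y <- yaml::read_yaml(path)
  weight_config(algorithm = y$algorithm, weights = y$weights,
                suspicious_threshold = y$suspicious_threshold,
                size_threshold_mm = y$size_threshold_mm %||% 6,
                age_band_edge_years = y$age_band_edge_years %||% 50,
                gate = y$gate %||% identical(y$algorithm, "pcsa"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shipped default weight configurations
#'
#' Loads one of the default configs installed with the package:
#' `"pcsa"` (gated, blood vessels scored 2 points, size and age terms),
#' `"mss"` (the four melanoma-associated SIAscopic features plus size and
#' age, no gate), or `"seven_point"` (three major items at 2 points, four
#' minor at 1, referral threshold 3).
#'
#' @param name one of `"pcsa"`, `"mss"`, `"seven_point"`.
#' @return a `weight_config`.
#' @export
default_config <- function(name = c("pcsa", "mss", "seven_point")) {
  name <- match.arg(name)
  load_weight_config(system.file("extdata", "configs",
                                 paste0(name, "_default.yaml"),
                                 package = "siascore", mustWork = TRUE))
}

# Gate ------------------------------------------------------------------------

#' Gate for non-melanocytic lesions
#'
#' Identifies lesions with SIAscopic features of the two benign
#' non-melanocytic lesion types that dominate primary-care case mix, before
#' any melanoma scoring: blood lacunes identify haemangioma; white dots on
#' the collagen view (the SIAscopic analogue of milia-like cysts) or a
#' cerebriform pattern on the total melanin view identify seborrhoeic
#' keratosis. Evaluation order is fixed: lacunes are checked first, so a
#' lesion with both haemangioma and seborrhoeic-keratosis features is
#' gated as haemangioma (its classification is benign either way).
#'
#' @param records a `lesion_cohort` (or any data frame with logical columns
#'   `blood_lacunes`, `collagen_white_dots`, `cerebriform_melanin`).
#' @return character vector: `"haemangioma"`, `"seborrhoeic_keratosis"` or
#'   `"none"` per lesion.
#' @export
gate_non_melanocytic <- function(records) {
  ifelse(records$blood_lacunes, "haemangioma",
         ifelse(records$collagen_white_dots | records$cerebriform_melanin,
                "seborrhoeic_keratosis", "none"))
}

# Scoring ---------------------------------------------------------------------

.size_indicator <- function(records, threshold_mm) {
  ind <- records$diameter_mm > threshold_mm
  use_flag <- is.na(records$diameter_mm)
  if (any(use_flag)) {
    if (threshold_mm != 6)
      stop("diameter_mm required when size_threshold_mm != 6 ",
           "(the diameter_gt_6mm flag encodes the 6 mm cut)")
    ind[use_flag] <- records$diameter_gt_6mm[use_flag]
  }
  ind
}

.age_indicator <- function(records, edge_years) {
  ind <- records$age_years >= edge_years
  use_band <- is.na(records$age_years)
  if (any(use_band)) {
    if (edge_years != 50)
      stop("age_years required when age_band_edge_years != 50 ",
           "(the age_band field encodes the 50-year cut)")
    ind[use_band] <- records$age_band[use_band] == ">=50"
  }
  ind
}

.sia_score <- function(records, config, required) {
  missing_w <- setdiff(required, names(config$weights))
  if (length(missing_w) > 0)
    stop("weight config for ", config$algorithm, " lacks required key(s): ",
         paste(missing_w, collapse = ", "))
  score <- integer(nrow(records))
  for (key in names(config$weights)) {
    ind <- switch(key,
      size_term = .size_indicator(records, config$size_threshold_mm),
      age_term = .age_indicator(records, config$age_band_edge_years),
      records[[key]])
    score <- score + as.integer(ind) * config$weights[[key]]
  }
  score
}

.score_result <- function(lesion_id, algorithm, gate, score, threshold) {
  classification <- ifelse(gate != "none", "benign",
                           ifelse(is.na(score), NA_character_,
                                  ifelse(score >= threshold,
                                         "suspicious", "benign")))
  score[gate != "none"] <- NA_integer_
  algorithm <- rep(algorithm, length.out = length(lesion_id))
  structure(data.frame(lesion_id = lesion_id, algorithm = algorithm,
                       gate = gate, score = as.integer(score),
                       classification = classification,
                       stringsAsFactors = FALSE),
            class = c("score_result", "data.frame"))
}

#' Score lesions with the Moncrieff scoring system
#'
#' Sums configured points for the melanoma-associated SIAscopic features
#' (dermal melanin, collagen holes, erythematous blush, blood displacement),
#' a size term (diameter above the configured cut) and an age term (age at
#' or above the configured band edge), with no non-melanocytic gate.
#'
#' @param records a `lesion_cohort`.
#' @param config a `weight_config`; must provide weights for the four
#'   melanoma features plus `size_term` and `age_term`.
#' @return a `score_result` data frame: `lesion_id`, `algorithm`, `gate`
#'   (always `"none"` here), integer `score`, and `classification`
#'   (`"suspicious"` iff score is at or above the threshold).
#' @export
moncrieff_score <- function(records, config = default_config("mss")) {
  required <- c("dermal_melanin", "collagen_holes", "erythematous_blush",
                "blood_displacement", "size_term", "age_term")
  score <- .sia_score(records, config, required)
  .score_result(records$lesion_id, config$algorithm,
                rep("none", nrow(records)), score,
                config$suspicious_threshold)
}

#' Classify lesions with the Primary Care Scoring Algorithm
#'
#' The PCSA first applies [gate_non_melanocytic()]: lesions with SIAscopic
#' features of haemangioma or seborrhoeic keratosis are classified benign
#' outright (the gate is recorded and no score assigned). Remaining lesions
#' are scored as in [moncrieff_score()] plus points for the presence of
#' blood vessels (default 2), and classified suspicious at or above the
#' configured threshold.
#'
#' @inheritParams moncrieff_score
#' @param config a `weight_config` with `gate = TRUE` and a `blood_vessels`
#'   weight in addition to the Moncrieff keys.
#' @return a `score_result` data frame; gated lesions have `score = NA` and
#'   `classification = "benign"`.
#' @export
pcsa_classify <- function(records, config = default_config("pcsa")) {
  required <- c("dermal_melanin", "collagen_holes", "erythematous_blush",
                "blood_displacement", "blood_vessels", "size_term",
                "age_term")
  gate <- if (config$gate) gate_non_melanocytic(records)
          else rep("none", nrow(records))
  score <- .sia_score(records, config, required)
  .score_result(records$lesion_id, config$algorithm, gate, score,
                config$suspicious_threshold)
}

#' Score lesions with the 7-point melanoma checklist
#'
#' Weighted sum of the seven checklist items: by default the three major
#' items (change in size, irregular shape, irregular colour) score 2 points
#' and the four minor items 1 point, with referral ("suspicious") at a
#' total of 3 or more. Lesions whose checklist block was not recorded get
#' `NA` score and classification and are excluded from downstream 7-point
#' analyses.
#'
#' @inheritParams moncrieff_score
#' @param config a `weight_config` over the seven checklist items.
#' @return a `score_result` data frame.
#' @export
seven_point_score <- function(records, config = default_config("seven_point")) {
  score <- integer(nrow(records))
  for (key in names(config$weights))
    score <- score + as.integer(records[[key]]) * config$weights[[key]]
  .score_result(records$lesion_id, config$algorithm,
                rep("none", nrow(records)), score,
                config$suspicious_threshold)
}

#' Score lesions with a named algorithm
#'
#' Dispatcher over the three scoring rules, used by the command-line
#' interface.
#'
#' @inheritParams moncrieff_score
#' @param algorithm `"pcsa"`, `"mss"` or `"seven_point"`.
#' @param config optional `weight_config`; defaults to the shipped config
#'   for the chosen algorithm.
#' @return a `score_result` data frame.
#' @export
score_lesions <- function(records, algorithm = c("pcsa", "mss", "seven_point"),
                          config = NULL) {
  algorithm <- match.arg(algorithm)
  config <- config %||% default_config(algorithm)
  switch(algorithm,
         pcsa = pcsa_classify(records, config),
         mss = moncrieff_score(records, config),
         seven_point = seven_point_score(records, config))
}
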