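# Domain vocabulary ----------------------------------------------------------

#' Field and label vocabularies for lesion records
#'
#' Canonical names used throughout the package: the eight expert-scored
#' SIAscopic features, the seven items of the 7-point melanoma checklist,
#' the twelve reference diagnoses, dataset tags, and reference-standard
#' tiers.
#'
#' @format Character vectors of canonical (snake_case) names.
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
sia_features <- c(
  "dermal_melanin", "collagen_holes", "erythematous_blush",
  "blood_displacement", "blood_vessels", "collagen_white_dots",
  "cerebriform_melanin", "blood_lacunes"
)

#' @rdname vocabulary
#' @export
seven_point_items <- c(
  "change_in_size", "irregular_shape", "irregular_colour",
  "diameter_ge_7mm", "inflammation", "oozing_or_crusting",
  "change_in_sensation"
)

#' @rdname vocabulary
#' @export
diagnosis_levels <- c(
  "naevus", "seborrhoeic_keratosis", "solar_lentigo", "basal_cell_carcinoma",
  "melanoma", "angiokeratoma", "dermatofibroma", "lentigo_maligna",
  "haemangioma", "lentigo_simplex", "ephilis", "papilloma"
)

#' @rdname vocabulary
#' @export
dataset_tags <- c("uk_development", "uk_validation", "australian_validation",
                  "other")

#' @rdname vocabulary
#' @export
reference_tiers <- c("histopathology", "in_person_expert", "image_expert")

# boolean token set accepted on ingest; anything else is an error, never
# silently coerced
.true_tokens <- c("true", "1", "yes")
.false_tokens <- c("false", "0", "no")
.na_tokens <- c("", "na")

.parse_flag <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(key))
  out[key %in% .true_tokens] <- TRUE
  out[key %in% .false_tokens] <- FALSE
  attr(out, "invalid") <- which(!is.na(key) & !(key %in%
    c(.true_tokens, .false_tokens, .na_tokens)))
  out
}

#' Normalise a reference-diagnosis label
#'
#' Maps printed diagnosis labels (any case, internal whitespace collapsed,
#' e.g. `"Seborrhoeic keratosis"`) onto the canonical snake_case levels in
#' [diagnosis_levels]. Unknown labels are an error, never coerced.
#'
#' @param x character vector of labels.
#' @return character vector of canonical labels.
#' @export
#' @examples
#' normalise_diagnosis(c("Melanoma", "Seborrhoeic  keratosis"))
normalise_diagnosis <- function(x) {
  key <- gsub("[ \t]+", "_", tolower(trimws(as.character(x))))
  hit <- match(key, diagnosis_levels)
  bad <- is.na(hit) & !is.na(key)
  if (any(bad)) {
    stop("unknown diagnosis label(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "), call. = FALSE)
  }
  diagnosis_levels[hit]
}

# Validation ------------------------------------------------------------------

.problem <- function(row, field, problem) {
  data.frame(row = row, field = field, problem = problem,
             stringsAsFactors = FALSE)
}

.mandatory_columns <- function() {
  c("lesion_id", sia_features, "reference_diagnosis", "reference_tier",
    "reference_suspicious")
}

#' Validate raw lesion rows into a typed lesion cohort
#'
#' Takes a data frame of raw (typically character) columns, as parsed from a
#' lesion CSV, and returns a fully typed cohort. Every violation in the
#' input is collected and reported in a single error, with row numbers
#' (counting data rows, header excluded).
#'
#' Rules enforced:
#' * all eight SIAscopic feature columns must be present and every value
#'   explicit (missing is an ingest error, not `FALSE`);
#' * boolean fields accept only `true/false/1/0/yes/no` (case-insensitive);
#' * `diameter_gt_6mm` must equal `diameter_mm > 6` whenever `diameter_mm`
#'   is given (contradictions are errors); when only `diameter_mm` is given
#'   the flag is derived;
#' * at least one of `age_years` (non-negative integer) or `age_band`
#'   (`"<50"` / `">=50"`) per row;
#' * `reference_diagnosis` must normalise to a known level; exactly one per
#'   record; `reference_tier` and `reference_suspicious` are mandatory;
#' * the seven checklist columns are optional as a block: either all seven
#'   are present in the file or none; within a row they must be all given
#'   or all missing (rows with a missing block are excluded from 7-point
#'   analyses, not imputed);
#' * `lesion_id` must be non-empty and unique.
#'
#' @param df data frame of raw values, one row per lesion.
#' @return a `lesion_cohort`: a data frame with typed columns.
#' @seealso [read_lesions()], [write_lesions()]
#' @export
validate_lesions <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  problems <- list()
  add <- function(p) problems[[length(problems) + 1L]] <<- p

  missing_cols <- setdiff(.mandatory_columns(), names(df))
  if (!("diameter_gt_6mm" %in% names(df)) && !("diameter_mm" %in% names(df)))
    missing_cols <- c(missing_cols, "diameter_mm|diameter_gt_6mm")
  if (!("age_years" %in% names(df)) && !("age_band" %in% names(df)))
    missing_cols <- c(missing_cols, "age_years|age_band")
  sp_present <- intersect(seven_point_items, names(df))
  if (length(sp_present) > 0 && length(sp_present) < length(seven_point_items))
    missing_cols <- c(missing_cols, setdiff(seven_point_items, sp_present))
  if (length(missing_cols) > 0) {
    add(.problem(NA_integer_, missing_cols, "mandatory column missing"))
    .stop_validation(do.call(rbind, problems))
  }

  out <- data.frame(lesion_id = trimws(as.character(df$lesion_id)),
                    stringsAsFactors = FALSE)
  bad_id <- which(is.na(out$lesion_id) | out$lesion_id == "")
  if (length(bad_id)) add(.problem(bad_id, "lesion_id", "missing lesion_id"))
  dup <- which(duplicated(out$lesion_id) & out$lesion_id != "")
  if (length(dup)) add(.problem(dup, "lesion_id", "duplicate lesion_id"))

  out$dataset_tag <- if ("dataset_tag" %in% names(df)) {
    tag <- tolower(trimws(as.character(df$dataset_tag)))
    tag[is.na(tag) | tag == ""] <- "other"
    bad <- which(!(tag %in% dataset_tags))
    if (length(bad)) add(.problem(bad, "dataset_tag", "unknown dataset tag"))
    tag
  } else rep("other", n)

  flag_col <- function(col, mandatory = TRUE) {
    v <- .parse_flag(df[[col]])
    inv <- attr(v, "invalid")
    if (length(inv)) add(.problem(inv, col, "unrecognised boolean token"))
    if (mandatory) {
      mis <- setdiff(which(is.na(v)), inv)
      if (length(mis)) add(.problem(mis, col, "missing value"))
    }
    attr(v, "invalid") <- NULL
    v
  }
  for (f in sia_features) out[[f]] <- flag_col(f)

  if (length(sp_present) == length(seven_point_items)) {
    sp <- lapply(seven_point_items, function(f) flag_col(f, mandatory = FALSE))
    names(sp) <- seven_point_items
    spm <- do.call(cbind, lapply(sp, is.na))
    mixed <- which(rowSums(spm) > 0 & rowSums(spm) < length(seven_point_items))
    if (length(mixed))
      add(.problem(mixed, "seven_point",
                   "checklist block partially missing (all or none)"))
    for (f in seven_point_items) out[[f]] <- sp[[f]]
  } else {
    for (f in seven_point_items) out[[f]] <- rep(NA, n)
  }

  if ("diameter_mm" %in% names(df)) {
    dm <- suppressWarnings(as.numeric(as.character(df$diameter_mm)))
    raw <- trimws(as.character(df$diameter_mm))
    badnum <- which(!is.na(raw) & raw != "" & is.na(dm))
    if (length(badnum)) add(.problem(badnum, "diameter_mm", "not a number"))
    nonpos <- which(!is.na(dm) & dm <= 0)
    if (length(nonpos)) add(.problem(nonpos, "diameter_mm", "diameter_mm <= 0"))
    dm[!is.na(dm) & dm <= 0] <- NA
    out$diameter_mm <- dm
  } else out$diameter_mm <- rep(NA_real_, n)

  if ("diameter_gt_6mm" %in% names(df)) {
    fl <- flag_col("diameter_gt_6mm", mandatory = FALSE)
    contra <- which(!is.na(fl) & !is.na(out$diameter_mm) &
                      fl != (out$diameter_mm > 6))
    if (length(contra))
      add(.problem(contra, "diameter_gt_6mm", "contradictory diameter fields"))
    derived <- is.na(fl) & !is.na(out$diameter_mm)
    fl[derived] <- out$diameter_mm[derived] > 6
    out$diameter_gt_6mm <- fl
  } else out$diameter_gt_6mm <- out$diameter_mm > 6
  mis <- which(is.na(out$diameter_gt_6mm))
  if (length(mis)) add(.problem(mis, "diameter_gt_6mm", "missing diameter"))

  if ("age_years" %in% names(df)) {
    ay <- suppressWarnings(as.numeric(as.character(df$age_years)))
    bad <- which(!is.na(ay) & (ay < 0 | ay != floor(ay)))
    if (length(bad))
      add(.problem(bad, "age_years", "not a non-negative integer"))
    ay[!is.na(ay) & (ay < 0 | ay != floor(ay))] <- NA
    out$age_years <- as.integer(ay)
  } else out$age_years <- rep(NA_integer_, n)

  if ("age_band" %in% names(df)) {
    ab <- trimws(as.character(df$age_band))
    ab[ab == ""] <- NA
    bad <- which(!is.na(ab) & !(ab %in% c("<50", ">=50")))
    if (length(bad)) add(.problem(bad, "age_band", "unknown age band"))
    out$age_band <- ab
  } else out$age_band <- rep(NA_character_, n)
  noage <- which(is.na(out$age_years) & is.na(out$age_band))
  if (length(noage)) add(.problem(noage, "age_years", "missing age"))

  out$sex <- if ("sex" %in% names(df)) {
    sx <- tolower(trimws(as.character(df$sex)))
    sx[is.na(sx) | sx == ""] <- "unknown"
    bad <- which(!(sx %in% c("male", "female", "unknown")))
    if (length(bad)) add(.problem(bad, "sex", "unknown sex"))
    sx
  } else rep("unknown", n)

  dx_raw <- trimws(as.character(df$reference_diagnosis))
  dx_key <- gsub("[ \t]+", "_", tolower(dx_raw))
  hit <- match(dx_key, diagnosis_levels)
  bad <- which(is.na(hit))
  if (length(bad)) add(.problem(bad, "reference_diagnosis",
                                paste0("unknown diagnosis label ",
                                       sQuote(dx_raw[bad]))))
  out$reference_diagnosis <- diagnosis_levels[hit]

  tier <- tolower(trimws(as.character(df$reference_tier)))
  bad <- which(!(tier %in% reference_tiers))
  if (length(bad)) add(.problem(bad, "reference_tier", "unknown tier"))
  out$reference_tier <- tier

  out$reference_suspicious <- flag_col("reference_suspicious")

  if (length(problems)) .stop_validation(do.call(rbind, problems))
  class(out) <- c("lesion_cohort", "data.frame")
  out
}

.stop_validation <- function(problems) {
  problems <- problems[order(problems$row), , drop = FALSE]
  lines <- sprintf("  row %s, %s: %s",
                   ifelse(is.na(problems$row), "-", problems$row),
                   problems$field, problems$problem)
  cond <- structure(
    class = c("lesion_validation_error", "error", "condition"),
    list(message = paste0("invalid lesion record(s):\n",
                          paste(unique(lines), collapse = "\n")),
         call = NULL, problems = problems))
  stop(cond)
}

# CSV I/O ---------------------------------------------------------------------

#' Read and write lesion CSV files
#'
#' The lesion CSV is UTF-8, comma-separated, with one header row and column
#' names exactly as in the typed cohort (see `inst/extdata/lesion-format.md`
#' for the shipped format reference). `read_lesions()` parses and validates;
#' `write_lesions()` writes booleans as `true`/`false` and missing values as
#' empty fields, so that a write/read round trip reproduces all field values.
#'
#' @param path file path.
#' @param x a `lesion_cohort` data frame.
#' @return `read_lesions()` returns a validated `lesion_cohort`;
#'   `write_lesions()` returns `path` invisibly.
#' @export
read_lesions <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = TRUE,
                  stringsAsFactors = FALSE)
  validate_lesions(raw)
}

#' @rdname read_lesions
#' @export
write_lesions <- function(x, path) {
  stopifnot(is.data.frame(x))
  fmt <- lapply(x, function(col) {
    if (is.logical(col)) ifelse(is.na(col), "", ifelse(col, "true", "false"))
    else if (is.numeric(col)) ifelse(is.na(col), "", format(col, digits = 15,
                                                            trim = TRUE))
    else ifelse(is.na(col), "", as.character(col))
  })
  write.csv(as.data.frame(fmt, stringsAsFactors = FALSE), path,
            row.names = FALSE)
  invisible(path)
}

#' Positive-label indicator for melanoma analyses
#'
#' @param records a `lesion_cohort`.
#' @param include_lentigo_maligna should lentigo maligna count as
#'   melanoma-positive (as in analyses pooling melanoma with lentigo
#'   maligna)? Default `TRUE`.
#' @return logical vector, `TRUE` where the reference diagnosis is melanoma
#'   (or lentigo maligna when included).
#' @export
melanoma_positive <- function(records, include_lentigo_maligna = TRUE) {
  pos <- c("melanoma", if (include_lentigo_maligna) "lentigo_maligna")
  records$reference_diagnosis %in% pos
}
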