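#' @importFrom rlang .data abort
#' @importFrom stats setNames
NULL

DRUG_CLASSES <- c("antihypertensive", "antihyperlipidemic")
GROUPS <- c("intervention", "control")
SEXES <- c("female", "male")

FILL_COLS <- c("patient_id", "drug_class", "subclass", "fill_date", "days_supply")
PATIENT_COLS <- c(
  "patient_id", "group", "age", "sex", "race_white", "diabetes", "bmi",
  "pcp_visits_per_year", "charlson", "enroll_start", "enroll_end"
)

# ISO-8601 parse that never consults the locale; returns NA for anything else.
parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

stop_format <- function(msg) abort(msg, class = "pdcadhere_format_error")
stop_validation <- function(msg) abort(msg, class = "pdcadhere_validation_error")

check_columns <- function(found, expected, what) {
  missing <- setdiff(expected, found)
  extra <- setdiff(found, expected)
  if (length(missing) || length(extra)) {
    stop_format(sprintf(
      "%s: header mismatch (missing: %s; unknown: %s)", what,
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"
    ))
  }
}

collect_row_errors <- function(bad, reason, acc) {
  if (any(bad)) c(acc, sprintf("row %d: %s", which(bad), reason)) else acc
}

raise_row_errors <- function(errors, what) {
  if (length(errors)) {
    stop_validation(sprintf(
      "%s: %d invalid row(s):\n%s", what, length(errors),
      paste(utils::head(errors, 20L), collapse = "\n")
    ))
  }
}

#' Read pharmacy fill records
#'
#' Parses a delimited text file of prescription fills into a validated tibble.
#' Expected columns: `patient_id, drug_class, subclass, fill_date, days_supply`.
#' Dates must be ISO-8601 (`YYYY-MM-DD`); `days_supply` must be a positive
#' integer; `drug_class` must be `antihypertensive` or `antihyperlipidemic`.
#' Row order is preserved. Invalid rows are collected and reported together
#' with their line numbers.
#'
#' @param path Path to a CSV (or other delimited) file with a header row.
#' @param sep Field separator, default `","`.
#' @return A tibble of fills with `fill_date` as `Date` and `days_supply` as
#'   integer.
#' @export
read_fills <- function(path, sep = ",") {
  if (!file.exists(path)) stop_format(sprintf("fills file not found: %s", path))
  raw <- data.table::fread(path, sep = sep, colClasses = "character",
                           na.strings = NULL, data.table = FALSE)
  check_columns(names(raw), FILL_COLS, "fills")
  raw <- raw[FILL_COLS]
  if (nrow(raw) == 0L) {
    return(tibble::tibble(
      patient_id = character(), drug_class = character(),
      subclass = character(), fill_date = as.Date(character()),
      days_supply = integer()
    ))
  }
  fill_date <- parse_iso_date(raw$fill_date)
  ds_num <- suppressWarnings(as.numeric(raw$days_supply))
  errs <- character()
  errs <- collect_row_errors(!raw$drug_class %in% DRUG_CLASSES,
                             "drug_class not one of antihypertensive/antihyperlipidemic", errs)
  errs <- collect_row_errors(is.na(fill_date), "unparseable fill_date (need YYYY-MM-DD)", errs)
  errs <- collect_row_errors(is.na(ds_num) | ds_num < 1 | ds_num != floor(ds_num),
                             "days_supply must be a positive integer", errs)
  errs <- collect_row_errors(!nzchar(raw$patient_id), "empty patient_id", errs)
  errs <- collect_row_errors(!nzchar(raw$subclass), "empty subclass", errs)
  raise_row_errors(errs, "fills")
  tibble::tibble(
    patient_id = raw$patient_id,
    drug_class = raw$drug_class,
    subclass = raw$subclass,
    fill_date = fill_date,
    days_supply = as.integer(ds_num)
  )
}

#' Read the patient roster
#'
#' Parses the roster CSV into a validated tibble. Expected columns:
#' `patient_id, group, age, sex, race_white, diabetes, bmi,
#' pcp_visits_per_year, charlson, enroll_start, enroll_end`.
#' `group` must be `intervention` or `control`; `patient_id` must be unique;
#' enrollment dates are ISO-8601 with `enroll_start < enroll_end`. `bmi` may
#' be missing (empty or `NA`); members with a missing adjustment covariate
#' are excluded from adjusted models downstream, with a logged count.
#'
#' @param path Path to the roster CSV.
#' @param sep Field separator, default `","`.
#' @return A tibble of patient records.
#' @export
read_patients <- function(path, sep = ",") {
  if (!file.exists(path)) stop_format(sprintf("patients file not found: %s", path))
  raw <- data.table::fread(path, sep = sep, colClasses = "character",
                           na.strings = NULL, data.table = FALSE)
  check_columns(names(raw), PATIENT_COLS, "patients")
  raw <- raw[PATIENT_COLS]
  if (nrow(raw) == 0L) {
    out <- tibble::tibble(
      patient_id = character(), group = character(), age = integer(),
      sex = character(), race_white = logical(), diabetes = logical(),
      bmi = numeric(), pcp_visits_per_year = numeric(), charlson = numeric(),
      enroll_start = as.Date(character()), enroll_end = as.Date(character())
    )
    return(out)
  }
  dup <- unique(raw$patient_id[duplicated(raw$patient_id)])
  if (length(dup)) {
    stop_validation(sprintf("patients: duplicate patient_id: %s",
                            paste(utils::head(dup, 10L), collapse = ", ")))
  }
  as_bool <- function(x) {
    v <- rep(NA, length(x))
    v[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
    v[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
    v
  }
  num_or_na <- function(x) {
    x[!nzchar(x) | toupper(x) == "NA"] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  age <- num_or_na(raw$age)
  es <- parse_iso_date(raw$enroll_start)
  ee <- parse_iso_date(raw$enroll_end)
  race_white <- as_bool(raw$race_white)
  diabetes <- as_bool(raw$diabetes)
  bmi <- num_or_na(raw$bmi)
  visits <- num_or_na(raw$pcp_visits_per_year)
  charlson <- num_or_na(raw$charlson)
  errs <- character()
  errs <- collect_row_errors(!raw$group %in% GROUPS, "group not intervention/control", errs)
  errs <- collect_row_errors(!raw$sex %in% SEXES, "sex not female/male", errs)
  errs <- collect_row_errors(is.na(age) | age < 0, "age must be a nonnegative number", errs)
  errs <- collect_row_errors(is.na(race_white), "race_white must be boolean", errs)
  errs <- collect_row_errors(is.na(diabetes), "diabetes must be boolean", errs)
  errs <- collect_row_errors(is.na(visits) | visits < 0, "pcp_visits_per_year must be >= 0", errs)
  errs <- collect_row_errors(is.na(charlson) | charlson < 0, "charlson must be >= 0", errs)
  errs <- collect_row_errors(is.na(es) | is.na(ee), "unparseable enrollment date", errs)
  errs <- collect_row_errors(!is.na(es) & !is.na(ee) & es >= ee,
                             "enroll_start must precede enroll_end", errs)
  raise_row_errors(errs, "patients")
  tibble::tibble(
    patient_id = raw$patient_id, group = raw$group, age = as.integer(age),
    sex = raw$sex, race_white = race_white, diabetes = diabetes, bmi = bmi,
    pcp_visits_per_year = visits, charlson = charlson,
    enroll_start = es, enroll_end = ee
  )
}

#' Write fills / patients tables
#'
#' Inverse of [read_fills()] / [read_patients()]: writes the canonical CSV
#' dialect (ISO dates, `.` decimal point) so that a read/write round trip is
#' lossless.
#'
#' @param x Tibble as returned by the corresponding reader.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fills <- function(x, path) {
  out <- x[FILL_COLS]
  out$fill_date <- format(out$fill_date, "%Y-%m-%d")
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_fills
#' @export
write_patients <- function(x, path) {
  out <- x[PATIENT_COLS]
  out$enroll_start <- format(out$enroll_start, "%Y-%m-%d")
  out$enroll_end <- format(out$enroll_end, "%Y-%m-%d")
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write and re-read an analysis results bundle
#'
#' Serialises a tibble of effect estimates (one row per [effect_estimate()])
#' to a JSON document with one entry per effect:
#' `{comparison, class, period, measure, estimate, ci_low, ci_high, p, method,
#' adjusted}`. Numbers are written at full precision so the round trip is
#' bit-exact.
#'
#' @param results Tibble of effect estimates (possibly zero rows).
#' @param path Output path for the JSON document.
#' @return `path` invisibly for `write_results()`; the tibble for
#'   `read_results()`.
#' @export
write_results <- function(results, path) {
  cols <- c("comparison", "class", "period", "measure", "estimate",
            "ci_low", "ci_high", "p", "method", "adjusted")
  for (col in setdiff(cols, names(results))) results[[col]] <- NA
  entries <- results[cols]
  doc <- list(format = "pdcadhere-effects", version = 1L,
              effects = entries)
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", dataframe = "rows")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(sprintf("cannot write results to %s: %s", path,
                                 conditionMessage(ok)),
                         class = "pdcadhere_io_error")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  eff <- doc$effects
  if (is.null(eff) || length(eff) == 0L || NROW(eff) == 0L) {
    return(tibble::tibble(
      comparison = character(), class = character(), period = character(),
      measure = character(), estimate = numeric(), ci_low = numeric(),
      ci_high = numeric(), p = numeric(), method = character(),
      adjusted = logical()
    ))
  }
  tibble::as_tibble(eff)
}
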