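#' Validate a patient-record data frame
#'
#' Checks the record invariants: unique non-empty patient identifiers, age
#' at least 18, sex in `male`/`female`, strictly positive weight and height,
#' non-negative analytes, ASA physical status an integer 1 to 6.  Any field
#' except `patient_id` may be `NA` (explicit missingness).  Missing columns
#' are added as all-`NA`.
#'
#' @param records A `data.frame` with a `patient_id` column.
#' @return The records, column-ordered and type-coerced.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"patient_id" %in% names(records)) {
    stop("records must have a patient_id column")
  }
  ids <- as.character(records$patient_id)
  if (any(is.na(ids) | !nzchar(ids))) stop("patient_id must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  numeric_fields <- setdiff(patient_fields, c("patient_id", "sex"))
  for (f in setdiff(patient_fields, names(records))) {
    records[[f]] <- rep(if (f == "sex") NA_character_ else NA_real_,
                        nrow(records))
  }
  out <- records[patient_fields]
  out$patient_id <- ids
  out$sex <- as.character(out$sex)
  known_sex <- !is.na(out$sex)
  if (any(!out$sex[known_sex] %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  for (f in numeric_fields) out[[f]] <- as.numeric(out[[f]])
  if (any(!is.na(out$age) & out$age < 18)) {
    stop("age must be >= 18 (pediatric patients are rejected at ingestion)")
  }
  for (f in c("abw", "height")) {
    if (any(!is.na(out[[f]]) & out[[f]] <= 0)) {
      stop(f, " must be > 0 when present")
    }
  }
  for (f in setdiff(numeric_fields, c("abw", "height"))) {
    v <- out[[f]]
    if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
      stop(f, " must be finite and >= 0 when present")
    }
  }
  bad_asaps <- !is.na(out$asaps) &
    (out$asaps < 1 | out$asaps > 6 | out$asaps != round(out$asaps))
  if (any(bad_asaps)) stop("asaps must be an integer in 1..6 when present")
  rownames(out) <- NULL
  out
}

#' Read a patient cohort from CSV
#'
#' Ingests a comma-separated file (header required, `.` decimal separator)
#' through the column mapping and source units declared in the
#' configuration, converting every analyte to canonical units.  Unmapped or
#' absent optional analytes become missing; a mapped column that is absent
#' from the file is an error.  Malformed numeric cells become missing with a
#' warning naming the row and column.  Duplicate patient identifiers are
#' rejected.
#'
#' @param path CSV file path.
#' @param cfg A [malnut_config()] object (column mapping and units).
#' @return A validated patient-record `data.frame` in canonical units.
#' @export
read_cohort <- function(path, cfg = malnut_config()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("input file is empty: ", path)
  cols <- cfg$columns
  if (!cols[["patient_id"]] %in% names(raw)) {
    stop("mapped column missing from input: ", cols[["patient_id"]])
  }
  # a field is required to exist only if its mapped name differs from the
  # default (an explicit mapping) — identity-mapped fields absent from the
  # file are simply missing data
  explicit <- names(cols)[cols != names(cols)]
  lost <- explicit[!cols[explicit] %in% names(raw)]
  if (length(lost)) {
    stop("mapped column(s) missing from input: ",
         paste(cols[lost], collapse = ", "))
  }

  parse_num <- function(field) {
    col <- cols[[field]]
    if (!col %in% names(raw)) {
      return(rep(NA_real_, nrow(raw)))
    }
    txt <- trimws(raw[[col]])
    txt[txt == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(val))
    for (i in bad) {
      warning(sprintf(
        "row %d, column '%s': malformed numeric '%s' treated as missing",
        i, col, txt[i]
      ), call. = FALSE)
    }
    val
  }

  rec <- data.frame(
    patient_id = trimws(raw[[cols[["patient_id"]]]]),
    stringsAsFactors = FALSE
  )
  rec$age <- parse_num("age")
  sex_col <- cols[["sex"]]
  rec$sex <- if (sex_col %in% names(raw)) {
    s <- tolower(trimws(raw[[sex_col]]))
    s[s == ""] <- NA_character_
    s[!is.na(s) & s %in% c("m", "male")] <- "male"
    s[!is.na(s) & s %in% c("f", "female")] <- "female"
    s
  } else {
    NA_character_
  }
  for (f in names(field_analytes)) {
    rec[[f]] <- to_canonical(parse_num(f), field_analytes[[f]],
                             cfg$units[[f]])
  }
  rec$asaps <- parse_num("asaps")
  validate_records(rec)
}

#' Write scored results to CSV
#'
#' One row per patient; per score, four columns: `<score>_value`,
#' `<score>_code`, `<score>_applicable`, `<score>_reason`.  Column order is
#' stable and the file round-trips: re-reading yields identical codes.
#'
#' @param cohort A `coded_cohort` from [score_cohort()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(cohort, path) {
  stopifnot(inherits(cohort, "coded_cohort"))
  wide <- cohort_wide(cohort)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(wide, con, row.names = FALSE, na = "", eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a scored CSV
#'
#' Inverse of [write_scores()] for inspection and round-trip checks.
#'
#' @param path CSV path written by [write_scores()].
#' @return A wide `data.frame` (one row per patient).
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$patient_id <- as.character(out$patient_id)
  for (nm in grep("_reason$", names(out), value = TRUE)) {
    out[[nm]][is.na(out[[nm]])] <- ""
  }
  for (nm in grep("_code$", names(out), value = TRUE)) {
    out[[nm]] <- as.integer(out[[nm]])
  }
  out
}
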