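# Reading and writing the cohort exam table.
#
# Schema: patient_id, eye in {OD, OS}, exam_date (ISO-8601), quality in
# {OK, YELLOW, RED}, Age (years), KmaxZonalMean3mm (D), RsF, BFSF, RmB (mm),
# LOGIK (unitless). An optional eye_id column (patient + side) is preserved;
# when absent it is derived as "<patient_id>_<eye>".

COHORT_REQUIRED_COLS <- c("patient_id", "eye", "exam_date", "quality",
                          KC_ALL_VARIABLES)

#' Write an exam table to CSV
#'
#' @param exams Exam data frame (or a `kc_cohort`, whose `$exams` is used).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(exams, path) {
  if (inherits(exams, "kc_cohort")) exams <- exams$exams
  exams <- validate_exam_table(exams)
  exams$exam_date <- format(exams$exam_date, "%Y-%m-%d")
  # %.17g guarantees an exact numeric round trip through the text file
  for (v in KC_ALL_VARIABLES) exams[[v]] <- sprintf("%.17g", exams[[v]])
  utils::write.csv(exams, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an exam table from CSV
#'
#' Validates the schema strictly: missing columns, unparsable dates, unknown
#' quality flags and non-positive measurements are rejected with the row and
#' column named.
#'
#' @param path CSV file written by [write_cohort()] or conforming to its
#'   schema.
#' @return A validated exam data frame; `exam_date` is a `Date`.
#' @export
read_cohort <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_exam_table(raw)
}

# Internal: coerce and validate an exam table against the schema.
validate_exam_table <- function(exams) {
  check_that(is.data.frame(exams), "exam table must be a data frame")
  missing <- setdiff(COHORT_REQUIRED_COLS, names(exams))
  check_that(length(missing) == 0L,
             "exam table is missing column(s): %s",
             paste(missing, collapse = ", "))
  if (nrow(exams) == 0L) {
    exams$exam_date <- as.Date(exams$exam_date)
    for (v in KC_ALL_VARIABLES) exams[[v]] <- as.numeric(exams[[v]])
    if (is.null(exams$eye_id)) {
      exams$eye_id <- character(0)
    }
    return(exams)
  }

  fail_at <- function(col, rows, what) {
    stop(sprintf("invalid exam table: %s in column '%s' at row(s) %s",
                 what, col, paste(utils::head(rows, 5L), collapse = ", ")),
         call. = FALSE)
  }

  if (!inherits(exams$exam_date, "Date")) {
    parsed <- as.Date(as.character(exams$exam_date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad) > 0L) fail_at("exam_date", bad, "unparsable ISO-8601 date")
    exams$exam_date <- parsed
  }

  bad <- which(!exams$eye %in% c("OD", "OS"))
  if (length(bad) > 0L) {
    fail_at("eye", bad, sprintf("unknown eye label '%s'", exams$eye[bad[1]]))
  }
  bad <- which(!exams$quality %in% KC_QUALITY_LEVELS)
  if (length(bad) > 0L) {
    fail_at("quality", bad,
            sprintf("unknown quality flag '%s'", exams$quality[bad[1]]))
  }

  for (v in KC_ALL_VARIABLES) {
    vals <- suppressWarnings(as.numeric(exams[[v]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0L) fail_at(v, bad, "non-numeric value")
    exams[[v]] <- vals
  }
  bad <- which(exams$Age <= 0)
  if (length(bad) > 0L) fail_at("Age", bad, "non-positive age")
  for (v in c("KmaxZonalMean3mm", "RsF", "BFSF", "RmB")) {
    bad <- which(exams[[v]] <= 0)
    if (length(bad) > 0L) fail_at(v, bad, "non-positive measurement")
  }

  if (is.null(exams$eye_id)) {
    exams$eye_id <- paste(exams$patient_id, exams$eye, sep = "_")
  }
  exams
}
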