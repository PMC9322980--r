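.cohortColumns <- c("record_id", "sex", "age_years", "insurance_type",
                    "admission_route", "treatment_outcome", "principal_dx",
                    "secondary_dx", "procedure_codes", "main_surgery_code")

.enumLevels <- list(
  sex = c("male", "female"),
  insurance_type = c("national_health", "medicaid_1", "medicaid_2", "other"),
  admission_route = c("emergency", "outpatient", "other"),
  treatment_outcome = c("improved", "not_improved", "death", "other")
)

# validate a raw character data.frame of discharge records; returns a list
# with the cleaned cohort and a data.frame of row-level problems
validateCohortFrame <- function(df) {
  problems <- data.frame(row = integer(0), field = character(0),
                         value = character(0), message = character(0))
  note <- function(rows, field, values, msg) {
    if (!length(rows)) return()
    problems <<- rbind(problems, data.frame(
      row = rows, field = field, value = as.character(values),
      message = msg, stringsAsFactors = FALSE))
  }
  for (f in names(.enumLevels)) {
    bad <- which(!df[[f]] %in% .enumLevels[[f]])
    note(bad, f, df[[f]][bad],
         sprintf("not one of {%s}", paste(.enumLevels[[f]], collapse = ", ")))
  }
  ageNum <- suppressWarnings(as.integer(df$age_years))
  bad <- which(is.na(ageNum) | ageNum < 0 |
                 ageNum != suppressWarnings(as.numeric(df$age_years)))
  note(bad, "age_years", df$age_years[bad], "not a non-negative integer")
  bad <- which(is.na(df$principal_dx) | !nzchar(trimws(df$principal_dx)))
  note(bad, "principal_dx", df$principal_dx[bad], "empty principal diagnosis")
  dup <- which(duplicated(df$record_id) | duplicated(df$record_id, fromLast = TRUE))
  note(dup, "record_id", df$record_id[dup], "duplicate record_id")
  df$age_years <- ageNum
  list(cohort = df, problems = problems)
}

#' Read a discharge-record cohort from delimited text
#'
#' Expects a header with the fixed schema `record_id, sex, age_years,
#' insurance_type, admission_route, treatment_outcome, principal_dx,
#' secondary_dx, procedure_codes, main_surgery_code`; the two list-valued
#' columns hold their codes joined by `listSep` inside a single cell. Rows
#' failing validation (out-of-vocabulary enum values, non-integer age, empty
#' principal diagnosis, duplicate ids) abort the read in strict mode; with
#' `strict = FALSE` they are dropped, logged via [message()], and attached as
#' the `"problems"` attribute.
#'
#' @param path file path.
#' @param delim field delimiter (default `","`).
#' @param listSep separator inside list-valued cells (default `";"`).
#' @param strict abort on any invalid row (default) instead of drop-and-log.
#' @return a `data.frame` of discharge records, one row per episode.
#' @seealso [writeCohort()], [filterCohort()]
#' @export
readCohort <- function(path, delim = ",", listSep = ";", strict = TRUE) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", quote = "\"",
                          na.strings = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(.cohortColumns, names(df))
  if (length(missing))
    stopf("cohort file missing required column(s): %s",
          paste(missing, collapse = ", "))
  df <- df[, .cohortColumns, drop = FALSE]
  if (nrow(df) == 0) {
    df$age_years <- integer(0)
    attr(df, "listSep") <- listSep
    return(df)
  }
  v <- validateCohortFrame(df)
  if (nrow(v$problems)) {
    desc <- sprintf("row %d: %s = %s (%s)", v$problems$row, v$problems$field,
                    sQuote(v$problems$value), v$problems$message)
    if (strict)
      stopf("invalid cohort rows:\n%s", paste(desc, collapse = "\n"))
    message("dropping ", length(unique(v$problems$row)),
            " invalid row(s):\n", paste(desc, collapse = "\n"))
    keep <- setdiff(seq_len(nrow(df)), v$problems$row)
    out <- v$cohort[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "problems") <- v$problems
    attr(out, "listSep") <- listSep
    return(out)
  }
  out <- v$cohort
  attr(out, "listSep") <- listSep
  out
}

#' Write a cohort back to delimited text
#'
#' Inverse of [readCohort()]: writing then re-reading a valid cohort
#' reproduces identical field values, and writing the same cohort twice
#' produces identical bytes.
#'
#' @param cohort a cohort `data.frame`.
#' @param path output file path.
#' @param delim,listSep as in [readCohort()] (`listSep` is not re-applied;
#'   list cells are stored as already-joined strings).
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path, delim = ",", listSep = ";") {
  df <- as.data.frame(cohort)[, .cohortColumns, drop = FALSE]
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Apply the study's cohort filter
#'
#' Retains adult episodes (age >= 19 years) whose principal diagnosis lies in
#' the malignant-neoplasm chapter C00--C97. Filtering is total (never errors)
#' and idempotent; counts of records dropped by reason are reported via
#' [message()] and attached as the `"dropped"` attribute.
#'
#' @param cohort a cohort `data.frame` from [readCohort()] or
#'   [generateCohort()].
#' @param minAge minimum age in years retained (default 19).
#' @param quiet suppress the drop-count message.
#' @return the filtered cohort `data.frame`.
#' @export
filterCohort <- function(cohort, minAge = 19L, quiet = FALSE) {
  if (!nrow(cohort)) return(cohort)
  adult <- cohort$age_years >= minAge
  malignant <- codeInRange(normalizeCode(cohort$principal_dx), "C00", "C979")
  dropped <- c(underage = sum(!adult),
               non_malignant_principal = sum(adult & !malignant))
  if (!quiet && sum(dropped) > 0)
    message("filterCohort: dropped ", dropped[["underage"]],
            " record(s) under age ", minAge, " and ",
            dropped[["non_malignant_principal"]],
            " with principal diagnosis outside C00-C97")
  out <- cohort[adult & malignant, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
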