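# Cohort table reading/writing, timecourse classification and summary
# statistics. The cohort schema mirrors a clinical characteristics table:
# one row per biopsied patient with demographics, diagnoses, disease
# timecourse, the signed interval between biosample collection and biopsy,
# and flags for CNS disease and vasculitis.

COHORT_COLUMNS <- c("study_id", "age", "sex", "clinical_dx", "path_dx",
                    "timecourse", "delta_days_to_biopsy", "cns_disease",
                    "vasculitis")
SEX_LEVELS <- c("m", "f")
TIMECOURSE_LEVELS <- c("acute", "subacute", "chronic")
CNS_LEVELS <- c("yes", "no", "unclear")
VASCULITIS_LEVELS <- c("definite_or_probable", "other")
MAX_DELTA_DAYS <- 30L

checkEnum <- function(values, levels, column) {
  bad <- which(!values %in% levels)
  if (length(bad))
    stop(sprintf("invalid value '%s' in column '%s' at row %d (allowed: %s)",
                 values[bad[1]], column, bad[1],
                 paste(levels, collapse = ", ")), call. = FALSE)
  invisible(values)
}

checkInteger <- function(values, column, allowNegative = FALSE) {
  num <- suppressWarnings(as.numeric(values))
  bad <- which(!is.finite(num) | num != round(num) |
                 (!allowNegative & num < 0))
  if (length(bad))
    stop(sprintf("column '%s' must hold %sintegers; offending row %d ('%s')",
                 column, if (allowNegative) "" else "non-negative ",
                 bad[1], values[bad[1]]), call. = FALSE)
  as.integer(num)
}

#' Validate a cohort data.frame
#'
#' Enforces the cohort schema: required columns, enumerated categories,
#' integer age and signed integer biosample-to-biopsy interval with
#' |days| <= 30 (the sample-inclusion window).
#'
#' @param cohort data.frame in the cohort schema.
#' @return The validated data.frame (types coerced), invisibly classed as-is.
#' @export
validateCohort <- function(cohort) {
  missing <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing))
    stop("cohort table misses required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cohort <- cohort[, COHORT_COLUMNS]
  if (nrow(cohort) == 0L) return(cohort)
  cohort$study_id <- as.character(cohort$study_id)
  if (anyDuplicated(cohort$study_id))
    stop("duplicated study_id values", call. = FALSE)
  cohort$age <- checkInteger(cohort$age, "age")
  cohort$delta_days_to_biopsy <-
    checkInteger(cohort$delta_days_to_biopsy, "delta_days_to_biopsy",
                 allowNegative = TRUE)
  tooFar <- which(abs(cohort$delta_days_to_biopsy) > MAX_DELTA_DAYS)
  if (length(tooFar))
    stop(sprintf("row %d: |delta_days_to_biopsy| exceeds the %d-day inclusion window",
                 tooFar[1], MAX_DELTA_DAYS), call. = FALSE)
  checkEnum(cohort$sex, SEX_LEVELS, "sex")
  checkEnum(cohort$timecourse, TIMECOURSE_LEVELS, "timecourse")
  checkEnum(cohort$cns_disease, CNS_LEVELS, "cns_disease")
  checkEnum(cohort$vasculitis, VASCULITIS_LEVELS, "vasculitis")
  cohort
}

#' Read a cohort table from CSV
#'
#' Comma-separated, UTF-8, header required, `NA` for missing optional
#' fields. Every row is validated against the cohort schema; invalid
#' enumeration values raise an error naming the row and column.
#'
#' @param path path to the CSV file.
#' @return A validated cohort data.frame (one row per patient).
#' @examples
#' tbl <- readCohortTable(system.file("extdata", "cohort_table1.csv",
#'                                    package = "nflaxon"))
#' nrow(tbl)
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validateCohort(raw)
}

#' Write a cohort table to CSV
#'
#' Inverse of [readCohortTable()]; a read/write round trip reproduces field
#' values exactly.
#'
#' @param cohort validated cohort data.frame.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  cohort <- validateCohort(cohort)
  write.csv(cohort, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Classify the disease timecourse from days since onset
#'
#' Biosample collection less than one week after disease onset or
#' exacerbation is "acute", 1--8 weeks (7--56 days, both inclusive)
#' "subacute", and beyond 8 weeks "chronic".
#'
#' @param daysSinceOnset non-negative days between onset/exacerbation and
#'   biosample collection (vectorised).
#' @return Character vector of `"acute"`, `"subacute"` or `"chronic"`.
#' @examples
#' classifyTimecourse(c(3, 7, 56, 90))
#' @export
classifyTimecourse <- function(daysSinceOnset) {
  if (any(!is.finite(daysSinceOnset)) || any(daysSinceOnset < 0))
    stop("daysSinceOnset must be non-negative", call. = FALSE)
  ifelse(daysSinceOnset < 7, "acute",
         ifelse(daysSinceOnset <= 56, "subacute", "chronic"))
}

#' Summarise a cohort
#'
#' Counts by sex, CNS-disease status and vasculitis diagnosis, the number of
#' vasculitis patients with an acute or subacute disease course, and the
#' median of the signed biosample-to-biopsy interval.
#'
#' @param cohort validated cohort data.frame (non-empty).
#' @return A [CohortSummary-class] object.
#' @examples
#' tbl <- readCohortTable(system.file("extdata", "cohort_table1.csv",
#'                                    package = "nflaxon"))
#' summarizeCohort(tbl)
#' @export
summarizeCohort <- function(cohort) {
  cohort <- validateCohort(cohort)
  if (nrow(cohort) == 0L)
    stop("cannot summarise an empty cohort", call. = FALSE)
  vasc <- cohort$vasculitis == "definite_or_probable"
  new("CohortSummary",
      nTotal = nrow(cohort),
      nMale = sum(cohort$sex == "m"),
      nFemale = sum(cohort$sex == "f"),
      nCnsYes = sum(cohort$cns_disease == "yes"),
      nVasculitis = sum(vasc),
      nVasculitisAcuteOrSubacute =
        sum(vasc & cohort$timecourse %in% c("acute", "subacute")),
      nOtherDx = sum(!vasc),
      medianDeltaDays = median(cohort$delta_days_to_biopsy))
}

#' Turn a CohortSummary into a one-row data.frame
#'
#' @param summary a [CohortSummary-class] object.
#' @return A one-row data.frame of the summary fields.
#' @export
cohortSummaryAsDataFrame <- function(summary) {
  stopifnot(is(summary, "CohortSummary"))
  data.frame(
    n_total = summary@nTotal, n_male = summary@nMale,
    n_female = summary@nFemale, n_cns_yes = summary@nCnsYes,
    n_vasculitis = summary@nVasculitis,
    n_vasculitis_acute_or_subacute = summary@nVasculitisAcuteOrSubacute,
    n_other_dx = summary@nOtherDx,
    median_delta_days = summary@medianDeltaDays
  )
}
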