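#' @name cohort_io
#' @title Cohort CSV input and output
#' @description
#' Cohorts are flat CSV tables with one row per patient and the fixed column
#' set `patient_id`, `sbp_baseline`, `dbp_baseline`, `meds_baseline`,
#' `sbp_discharge`, `dbp_discharge`, `meds_discharge`. Blood pressures are
#' decimals in mmHg; medication counts must be non-negative integers at
#' patient level. Files are UTF-8, comma-separated, with a `.` decimal mark;
#' numbers are serialised at full precision so a write/read round trip
#' reproduces every field exactly. Incomplete rows are rejected, never
#' imputed.
NULL

cohort_columns <- c("patient_id",
                    "sbp_baseline", "dbp_baseline", "meds_baseline",
                    "sbp_discharge", "dbp_discharge", "meds_discharge")

#' Validate a cohort table
#'
#' Checks the schema and every row's invariants: finite positive pressures
#' with systolic above diastolic at both timepoints, integer non-negative
#' medication counts, no missing values, unique patient identifiers. Errors
#' cite the offending column and row.
#'
#' @param cohort A data frame.
#' @return The validated cohort (invisibly usable), with columns in schema
#'   order and `patient_id` as character.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame", call. = FALSE)
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- cohort[cohort_columns]
  cohort$patient_id <- as.character(cohort$patient_id)
  if (nrow(cohort) == 0L) return(cohort)

  num_cols <- cohort_columns[-1]
  for (cl in num_cols) {
    v <- cohort[[cl]]
    if (!is.numeric(v)) {
      stop("cohort validation error: column '", cl, "' is not numeric",
           call. = FALSE)
    }
    cohort[[cl]] <- as.double(v)
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop("cohort validation error: row ", bad[1], ", column '", cl,
           "': missing or non-finite value", call. = FALSE)
    }
  }
  for (tp in c("baseline", "discharge")) {
    sbp <- cohort[[paste0("sbp_", tp)]]
    dbp <- cohort[[paste0("dbp_", tp)]]
    meds <- cohort[[paste0("meds_", tp)]]
    bad <- which(sbp <= 0 | dbp <= 0)
    if (length(bad) > 0L) {
      stop("cohort validation error: row ", bad[1], ", ", tp,
           " blood pressure must be positive", call. = FALSE)
    }
    bad <- which(sbp <= dbp)
    if (length(bad) > 0L) {
      stop("cohort validation error: row ", bad[1], ", column 'sbp_", tp,
           "': systolic must exceed diastolic", call. = FALSE)
    }
    bad <- which(meds < 0 | meds != round(meds))
    if (length(bad) > 0L) {
      stop("cohort validation error: row ", bad[1], ", column 'meds_", tp,
           "': medication count must be a non-negative integer", call. = FALSE)
    }
  }
  dup <- duplicated(cohort$patient_id)
  if (any(dup)) {
    stop("cohort validation error: duplicate patient_id '",
         cohort$patient_id[which(dup)[1]], "'", call. = FALSE)
  }
  cohort
}

#' Read a cohort CSV file
#'
#' @param path Path to a CSV file in the schema described in [cohort_io].
#' @return A validated cohort data frame. A header-only file yields an empty
#'   cohort; analysis functions reject empty cohorts at their own boundary.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(generate_cohort(seed = 1), f)
#' coh <- read_cohort(f)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  validate_cohort(raw)
}

# Shortest decimal representation that round-trips the double exactly.
format_full_precision <- function(x) {
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g", width = 1)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

#' Write a cohort (or any cohort-shaped table) to CSV
#'
#' Numeric fields are serialised with enough digits that re-reading
#' reproduces the stored doubles bit-exactly.
#'
#' @param cohort A cohort data frame (extra columns, e.g. labels from
#'   [classify_cohort()], are preserved).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame", call. = FALSE)
  out <- cohort
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- format_full_precision(out[[cl]])
    if (is.factor(out[[cl]])) out[[cl]] <- as.character(out[[cl]])
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
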