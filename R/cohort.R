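#' @keywords internal
"_PACKAGE"

#' Cohort group labels
#'
#' The three diagnostic groups of the screening cohort: connective tissue
#' disease without pulmonary hypertension (`CTD`), connective tissue disease
#' with pulmonary arterial hypertension (`CTD_PAH`), and pulmonary
#' hypertension of other etiology (`PH_OTHER`).
#'
#' @return Character vector of the three valid group labels.
#' @export
cohort_groups <- function() c("CTD", "CTD_PAH", "PH_OTHER")

# numeric per-patient fields; everything physiologic must be > 0 when present
cohort_numeric_fields <- function() {
  c("age", "fvc_pct", "fev1_pct", "dlco_pct", "lvef_pct", "spap_mmhg",
    "peak_vo2", "vt1_pct_peak_vo2", "ve_vco2_slope", "petco2_basal",
    "pulse_o2_peak_pct", "eqco2_basal", "duration_min", "workload_watts",
    "rer")
}

cohort_fields <- function() c("id", "group", "sex", cohort_numeric_fields())

#' Validate a cohort data frame
#'
#' Checks that a data frame conforms to the per-patient record contract:
#' required columns present, group labels among [cohort_groups()], sex coded
#' `M`/`F`, and all physiologic fields strictly positive where not missing.
#' CPET fields may be missing (`NA`); identity fields may not.
#'
#' @param cohort A data frame of patient records.
#' @return The validated data frame, invisibly.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_fields(), names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(cohort) == 0L) return(invisible(cohort))
  bad_group <- which(!cohort$group %in% cohort_groups())
  if (length(bad_group) > 0L)
    stop(sprintf("row %d: unknown group label '%s'",
                 bad_group[1L], cohort$group[bad_group[1L]]), call. = FALSE)
  bad_sex <- which(!cohort$sex %in% c("M", "F"))
  if (length(bad_sex) > 0L)
    stop(sprintf("row %d: sex must be 'M' or 'F', got '%s'",
                 bad_sex[1L], cohort$sex[bad_sex[1L]]), call. = FALSE)
  for (v in cohort_numeric_fields()) {
    x <- cohort[[v]]
    if (!is.numeric(x))
      stop(sprintf("column '%s' must be numeric", v), call. = FALSE)
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad) > 0L)
      stop(sprintf("row %d: '%s' must be strictly positive, got %g",
                   bad[1L], v, x[bad[1L]]), call. = FALSE)
  }
  invisible(cohort)
}

#' Read a cohort CSV file
#'
#' Reads a comma-separated cohort file (UTF-8, `.` decimal separator, one
#' header row). Missing CPET values are encoded as empty cells. Unknown
#' columns are preserved. Group labels and numeric columns are validated
#' with row-level error messages.
#'
#' @param path Path to a CSV file with a header naming the patient fields.
#' @return A data frame of patient records.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(cohort_fields(), names(raw))
  if (length(missing_cols) > 0L)
    stop("cohort file is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (v in cohort_numeric_fields()) {
    x <- trimws(raw[[v]])
    x[x == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad) > 0L)
      stop(sprintf("row %d: non-numeric value '%s' in column '%s'",
                   bad[1L], x[bad[1L]], v), call. = FALSE)
    raw[[v]] <- num
  }
  validate_cohort(raw)
  raw
}

#' Write a cohort to a CSV file
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` recovers the
#' records up to floating-point formatting. Missing values become empty cells.
#'
#' @param cohort A validated cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  for (v in cohort_numeric_fields())
    out[[v]] <- ifelse(is.na(out[[v]]), "",
                       format(out[[v]], digits = 15, trim = TRUE,
                              scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
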