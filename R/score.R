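#' Composite-score thresholds
#'
#' The three cutoffs of the composite CPET score. A patient accrues one
#' point for each of: peak VO2 at or below `peak_vo2_max` (ml/kg/min),
#' VE/VCO2 slope strictly above `ve_vco2_min`, and basal PetCO2 at or below
#' `petco2_max` (mmHg). Defaults are the Youden-selected cutoffs of the
#' screening analysis this package implements; alternative (e.g. re-derived)
#' cutoffs can be injected.
#'
#' @param peak_vo2_max Peak VO2 cutoff, ml/kg/min (point if value is <= it).
#' @param ve_vco2_min VE/VCO2 slope cutoff (point if value is strictly > it).
#' @param petco2_max Basal PetCO2 cutoff, mmHg (point if value is <= it).
#' @return An object of class `score_thresholds`.
#' @export
score_thresholds <- function(peak_vo2_max = 14.1, ve_vco2_min = 33.96,
                             petco2_max = 27.2) {
  vals <- c(peak_vo2_max, ve_vco2_min, petco2_max)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all three cutoffs must be positive", call. = FALSE)
  structure(list(peak_vo2_max = peak_vo2_max, ve_vco2_min = ve_vco2_min,
                 petco2_max = petco2_max), class = "score_thresholds")
}

#' Composite CPET score for one or more patients
#'
#' Sum of three indicator conditions: `peak_vo2 <= peak_vo2_max`,
#' `ve_vco2_slope > ve_vco2_min`, `petco2_basal <= petco2_max`.
#' Vectorised; a patient missing any of the three inputs receives `NA`
#' (a missing-data signal — patients are never partially scored).
#'
#' @param peak_vo2 Peak oxygen uptake, ml/kg/min.
#' @param ve_vco2_slope Ventilatory efficiency slope (dimensionless).
#' @param petco2_basal Resting end-tidal CO2 pressure, mmHg.
#' @param thresholds A [score_thresholds()] object.
#' @return Integer score(s) in `0:3`, `NA` where any input is missing.
#' @export
#' @examples
#' score_patient(12.5, 40.4, 25.0)  # 3
#' score_patient(18.4, 29.1, 29.2)  # 0
score_patient <- function(peak_vo2, ve_vco2_slope, petco2_basal,
                          thresholds = score_thresholds()) {
  stopifnot(inherits(thresholds, "score_thresholds"))
  n <- length(peak_vo2)
  if (length(ve_vco2_slope) != n || length(petco2_basal) != n)
    stop("score inputs must have equal length", call. = FALSE)
  if (any(peak_vo2 <= 0, na.rm = TRUE) ||
      any(ve_vco2_slope <= 0, na.rm = TRUE) ||
      any(petco2_basal <= 0, na.rm = TRUE))
    stop("score inputs must be strictly positive", call. = FALSE)
  as.integer((peak_vo2 <= thresholds$peak_vo2_max) +
             (ve_vco2_slope > thresholds$ve_vco2_min) +
             (petco2_basal <= thresholds$petco2_max))
}

#' Score distribution by disease status
#'
#' Tabulates the composite score against PAH status among connective tissue
#' disease patients (groups `CTD` and `CTD_PAH`; other groups are excluded).
#' Patients with any missing score input are tallied separately, never
#' silently scored.
#'
#' @param cohort A cohort data frame (see [validate_cohort()]).
#' @param thresholds A [score_thresholds()] object.
#' @return An object of class `score_distribution`: a list with `counts`
#'   (2 x 4 integer matrix, rows `CTD`/`CTD_PAH`, columns scores 0-3) and
#'   `n_missing` (named count of unscoreable patients per status).
#' @export
score_distribution <- function(cohort, thresholds = score_thresholds()) {
  validate_cohort(cohort)
  keep <- cohort$group %in% c("CTD", "CTD_PAH")
  cohort <- cohort[keep, , drop = FALSE]
  counts <- matrix(0L, 2L, 4L,
                   dimnames = list(c("CTD", "CTD_PAH"), as.character(0:3)))
  n_missing <- c(CTD = 0L, CTD_PAH = 0L)
  if (nrow(cohort) > 0L) {
    s <- score_patient(cohort$peak_vo2, cohort$ve_vco2_slope,
                       cohort$petco2_basal, thresholds)
    for (g in c("CTD", "CTD_PAH")) {
      sg <- s[cohort$group == g]
      n_missing[[g]] <- sum(is.na(sg))
      tab <- table(factor(sg[!is.na(sg)], levels = 0:3))
      counts[g, ] <- as.integer(tab)
    }
  }
  structure(list(counts = counts, n_missing = n_missing),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("Composite CPET score by PAH status (CTD patients)\n")
  print(x$counts)
  if (any(x$n_missing > 0L))
    cat("unscoreable (missing inputs):",
        paste(names(x$n_missing), x$n_missing, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}
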