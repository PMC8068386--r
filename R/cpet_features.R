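#' Construct a breath-by-breath CPET series
#'
#' Holds the time-aligned gas-exchange channels of one incremental test plus
#' the protocol phase markers. Markers are indices into the series: end of
#' rest, start of loaded exercise, and end of the isocapnic buffering period.
#' Buffering-end is supplied, not detected.
#'
#' @param time_s Strictly increasing sample times, seconds.
#' @param ve_l_min Minute ventilation, L/min.
#' @param vo2_ml_min Oxygen uptake, ml/min.
#' @param vco2_ml_min Carbon dioxide output, ml/min.
#' @param rest_end,loaded_start,buffering_end Phase-marker indices with
#'   `rest_end <= loaded_start < buffering_end`.
#' @return An object of class `breath_series`.
#' @export
breath_series <- function(time_s, ve_l_min, vo2_ml_min, vco2_ml_min,
                          rest_end, loaded_start, buffering_end) {
  m <- length(time_s)
  if (length(ve_l_min) != m || length(vo2_ml_min) != m ||
      length(vco2_ml_min) != m)
    stop("all channels must have equal length", call. = FALSE)
  if (m < 2L || any(diff(time_s) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(ve_l_min < 0) || any(vo2_ml_min < 0) || any(vco2_ml_min < 0))
    stop("gas-exchange values must be nonnegative", call. = FALSE)
  idx <- c(rest_end, loaded_start, buffering_end)
  if (any(idx < 1L) || any(idx > m) || any(idx != round(idx)))
    stop("phase markers must be indices into the series", call. = FALSE)
  if (!(rest_end <= loaded_start && loaded_start < buffering_end))
    stop("phase markers must satisfy rest_end <= loaded_start < buffering_end",
         call. = FALSE)
  structure(list(time_s = as.numeric(time_s), ve_l_min = as.numeric(ve_l_min),
                 vo2_ml_min = as.numeric(vo2_ml_min),
                 vco2_ml_min = as.numeric(vco2_ml_min),
                 rest_end = as.integer(rest_end),
                 loaded_start = as.integer(loaded_start),
                 buffering_end = as.integer(buffering_end)),
            class = "breath_series")
}

#' Ventilatory efficiency slope (VE vs VCO2)
#'
#' Ordinary least-squares slope of minute ventilation (L/min) on carbon
#' dioxide output (converted to L/min), fitted over the window from one
#' minute after the start of loaded exercise to the end of the isocapnic
#' buffering period. The slope is dimensionless.
#'
#' @param series A [breath_series()].
#' @return The fitted slope (single numeric).
#' @export
ve_vco2_slope <- function(series) {
  stopifnot(inherits(series, "breath_series"))
  t0 <- series$time_s[series$loaded_start] + 60
  t1 <- series$time_s[series$buffering_end]
  idx <- which(series$time_s >= t0 & series$time_s <= t1)
  if (length(idx) < 3L)
    stop("insufficient data: fewer than 3 samples in the slope window",
         call. = FALSE)
  vco2_l <- series$vco2_ml_min[idx] / 1000
  if (stats::var(vco2_l) == 0)
    stop("insufficient data: zero VCO2 variance in the slope window",
         call. = FALSE)
  unname(stats::coef(stats::lm(series$ve_l_min[idx] ~ vco2_l))[2L])
}

#' Peak oxygen uptake from 10-second averages
#'
#' Averages VO2 within consecutive non-overlapping 10-s time bins and returns
#' the maximum bin mean, the conventional definition of peak VO2 on
#' breath-by-breath data.
#'
#' @param series A [breath_series()].
#' @return Peak VO2 in ml/min.
#' @export
peak_vo2_10s <- function(series) {
  stopifnot(inherits(series, "breath_series"))
  bins <- floor((series$time_s - series$time_s[1L]) / 10)
  max(tapply(series$vo2_ml_min, bins, mean))
}

#' First ventilatory threshold by the V-slope method
#'
#' Locates the point where VCO2 starts rising faster than VO2: a two-segment
#' piecewise-linear least-squares fit of VCO2 on VO2 over the loaded-exercise
#' samples, with the breakpoint chosen to minimise the total residual sum of
#' squares subject to the second slope exceeding the first. At least 3 points
#' are required on each side of a candidate breakpoint. When no candidate
#' satisfies the slope constraint the threshold is reported as not detected
#' (this is a signal, not an error — e.g. a perfectly linear gas-exchange
#' relationship).
#'
#' @param series A [breath_series()].
#' @param peak_vo2 Peak VO2 (ml/min) used for the percent-of-peak output;
#'   defaults to [peak_vo2_10s()] of the series.
#' @return A list: `detected` (logical), `vt1_vo2` (ml/min at the
#'   breakpoint, `NA` if not detected), `vt1_pct_peak` (percent of peak VO2).
#' @export
detect_vt1_vslope <- function(series, peak_vo2 = peak_vo2_10s(series)) {
  stopifnot(inherits(series, "breath_series"))
  idx <- series$loaded_start:series$buffering_end
  if (length(idx) < 8L)
    stop("insufficient data: V-slope fit requires >= 8 exercise samples",
         call. = FALSE)
  ord <- order(series$vo2_ml_min[idx])
  x <- series$vo2_ml_min[idx][ord]
  y <- series$vco2_ml_min[idx][ord]
  m <- length(x)
  ols <- function(xs, ys) {
    xc <- xs - mean(xs)
    den <- sum(xc^2)
    if (den == 0) return(list(slope = NA_real_, rss = Inf))
    b <- sum(xc * (ys - mean(ys))) / den
    a <- mean(ys) - b * mean(xs)
    list(slope = b, rss = sum((ys - a - b * xs)^2))
  }
  best <- NULL
  for (b in 3:(m - 3L)) {
    f1 <- ols(x[1:b], y[1:b])
    f2 <- ols(x[(b + 1L):m], y[(b + 1L):m])
    if (!is.finite(f1$slope) || !is.finite(f2$slope)) next
    tol <- max(1e-8, 1e-8 * abs(f1$slope))
    if (f2$slope - f1$slope <= tol) next
    rss <- f1$rss + f2$rss
    if (is.null(best) || rss < best$rss) best <- list(b = b, rss = rss)
  }
  if (is.null(best))
    return(list(detected = FALSE, vt1_vo2 = NA_real_,
                vt1_pct_peak = NA_real_))
  vt1 <- x[best$b]
  list(detected = TRUE, vt1_vo2 = vt1, vt1_pct_peak = 100 * vt1 / peak_vo2)
}

#' Maximal-effort criterion
#'
#' A test is taken as maximal when the respiratory exchange ratio
#' (RER = VCO2/VO2) is strictly above 1.10.
#'
#' @param rer Positive respiratory exchange ratio.
#' @return `TRUE` iff `rer > 1.10`.
#' @export
is_maximal_effort <- function(rer) {
  if (!is.numeric(rer) || any(!is.finite(rer)) || any(rer <= 0))
    stop("rer must be positive", call. = FALSE)
  rer > 1.10
}
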