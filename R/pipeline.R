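#' Pipeline configuration
#'
#' Collects everything one analysis run depends on: the input mode (a
#' synthetic cohort or an existing CSV), the group specifications for
#' synthesis, the score thresholds, the assumed pre-test PAH prevalence
#' among CTD patients (default 10%), the confidence level, and the RNG seed.
#'
#' @param input `"synthetic"` or `"csv"`; exactly one input mode is active.
#' @param csv_path Cohort CSV path, required when `input = "csv"`.
#' @param specs Group specifications for synthesis
#'   ([default_group_specs()]).
#' @param thresholds [score_thresholds()] used for scoring and the
#'   single-marker accuracy panels.
#' @param prevalence Pre-test prevalence in `(0, 1)`, default 0.10.
#' @param level Confidence level in `(0, 1)`, default 0.95.
#' @param seed Integer seed (synthesis only).
#' @param use_youden Re-derive the three marker cutoffs from the data by
#'   [youden_optimal()] instead of using the configured thresholds.
#' @param out_dir Optional output directory for the report files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = c("synthetic", "csv"), csv_path = NULL,
                            specs = default_group_specs(),
                            thresholds = score_thresholds(),
                            prevalence = 0.10, level = 0.95, seed = 1L,
                            use_youden = FALSE, out_dir = NULL) {
  input <- match.arg(input)
  if (input == "csv" && (is.null(csv_path) || !file.exists(csv_path)))
    stop("input = 'csv' requires a readable csv_path", call. = FALSE)
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)", call. = FALSE)
  stopifnot(inherits(thresholds, "score_thresholds"))
  structure(list(input = input, csv_path = csv_path, specs = specs,
                 thresholds = thresholds, prevalence = prevalence,
                 level = level, seed = as.integer(seed),
                 use_youden = isTRUE(use_youden), out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

# marker -> orientation + strict-at-cutoff rule + configured cutoff
marker_rules <- function(thresholds) {
  list(
    peak_vo2 = list(orientation = "lower_is_diseased", strict = FALSE,
                    cutoff = thresholds$peak_vo2_max),
    ve_vco2_slope = list(orientation = "higher_is_diseased", strict = TRUE,
                         cutoff = thresholds$ve_vco2_min),
    petco2_basal = list(orientation = "lower_is_diseased", strict = FALSE,
                        cutoff = thresholds$petco2_max))
}

#' Run the full screening analysis
#'
#' Generates or reads the cohort, scores every CTD patient on the composite
#' scale, tabulates the score against PAH status, evaluates each single
#' marker (ROC, AUC with DeLong interval, accuracy panel at its cutoff) and
#' the composite score at >= 3 points, runs the trend test on the score
#' distribution and the Kruskal-Wallis comparison across all three groups.
#' Deterministic given the configuration and seed. Patients with missing
#' score inputs are excluded from the diagnostic analyses and counted in the
#' score distribution's missing tally.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `cpet_report`: a list with the scored cohort,
#'   score distribution, per-marker ROC curves and accuracy panels, the
#'   composite panel, the trend test, the group-comparison table and the
#'   configuration hash. Written to `config$out_dir` as CSV files when set.
#' @export
#' @examples
#' rep <- run_pipeline(pipeline_config(seed = 7))
#' rep$composite$accuracy
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (config$input == "synthetic")
    generate_cohort(config$specs, config$seed)
  else read_cohort(config$csv_path)

  ctd <- cohort[cohort$group %in% c("CTD", "CTD_PAH"), , drop = FALSE]
  scoreable <- !is.na(ctd$peak_vo2) & !is.na(ctd$ve_vco2_slope) &
    !is.na(ctd$petco2_basal)
  if (sum(scoreable) == 0L)
    stop("no scoreable patients", call. = FALSE)
  ctd_s <- ctd[scoreable, , drop = FALSE]
  diseased <- ctd_s$group == "CTD_PAH"
  if (!any(diseased) || all(diseased))
    stop("need both CTD and CTD_PAH patients for the diagnostic analysis",
         call. = FALSE)

  thresholds <- config$thresholds
  markers <- list()
  rules <- marker_rules(thresholds)
  youden_cuts <- list()
  for (mk in names(rules)) {
    rule <- rules[[mk]]
    curve <- roc_curve(ctd_s[[mk]], diseased, rule$orientation)
    cutoff <- rule$cutoff
    if (config$use_youden) {
      cutoff <- youden_optimal(curve)$threshold
      youden_cuts[[mk]] <- cutoff
    }
    tab <- confusion_at_threshold(ctd_s[[mk]], diseased, cutoff,
                                  rule$orientation, strict = rule$strict)
    markers[[mk]] <- list(
      roc = curve, auc = auc_ci(curve, config$level), cutoff = cutoff,
      accuracy = accuracy_report(tab, config$prevalence, config$level))
  }
  if (config$use_youden)
    thresholds <- score_thresholds(youden_cuts$peak_vo2,
                                   youden_cuts$ve_vco2_slope,
                                   youden_cuts$petco2_basal)

  scores <- score_patient(ctd_s$peak_vo2, ctd_s$ve_vco2_slope,
                          ctd_s$petco2_basal, thresholds)
  dist <- score_distribution(cohort, thresholds)
  comp_tab <- confusion_at_threshold(scores, diseased, 3,
                                     "higher_is_diseased")
  comp_roc <- roc_curve(scores, diseased, "higher_is_diseased")
  trend <- chi2_trend(events = dist$counts["CTD_PAH", ],
                      totals = colSums(dist$counts))

  scored <- cohort
  scored$score <- NA_integer_
  scored$score[match(ctd_s$id, cohort$id)] <- scores

  bundle <- structure(list(
    config = config, config_hash = config_hash(config), cohort = scored,
    thresholds = thresholds, distribution = dist, markers = markers,
    composite = list(roc = comp_roc, auc = auc_ci(comp_roc, config$level),
                     accuracy = accuracy_report(comp_tab, config$prevalence,
                                                config$level)),
    trend = trend,
    group_comparison = compare_groups(cohort)), class = "cpet_report")
  if (!is.null(config$out_dir)) write_report_files(bundle, config$out_dir)
  bundle
}

write_report_files <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- bundle$cohort
  cohort$score <- ifelse(is.na(cohort$score), "", cohort$score)
  utils::write.csv(cohort, file.path(dir, "cohort_scored.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(bundle$distribution$counts),
                   file.path(dir, "score_distribution.csv"))
  utils::write.csv(bundle$group_comparison,
                   file.path(dir, "group_stats.csv"), row.names = FALSE)
  for (mk in names(bundle$markers)) {
    curve <- bundle$markers[[mk]]$roc
    utils::write.csv(data.frame(threshold = curve$thresholds,
                                sensitivity = curve$sensitivity,
                                specificity = curve$specificity),
                     file.path(dir, paste0("roc_", mk, ".csv")),
                     row.names = FALSE)
  }
  writeLines(render_tables(bundle), file.path(dir, "report.txt"))
  invisible(dir)
}

fmt_iqr <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.1f (%.1f-%.1f)", q[1L], q[2L], q[3L])
}

#' Render the report bundle as text tables
#'
#' Pure formatting of a [run_pipeline()] bundle: per-group medians with
#' interquartile ranges ("median (q1-q3)"), the score-by-status contingency,
#' the accuracy panels (percentages to one decimal) and the test statistics
#' (one decimal). No randomness, no file access.
#'
#' @param bundle A `cpet_report` object.
#' @return Character vector of report lines.
#' @export
render_tables <- function(bundle) {
  stopifnot(inherits(bundle, "cpet_report"))
  for (part in c("cohort", "distribution", "markers", "composite", "trend",
                 "group_comparison"))
    if (is.null(bundle[[part]]))
      stop("report bundle is missing component '", part, "'", call. = FALSE)
  disp <- c(CTD = "CTDs", CTD_PAH = "CTDs-PAH", PH_OTHER = "PH-other")
  lines <- c(sprintf("CPET screening report [config %s]", bundle$config_hash),
             "", "== Cohort summaries, median (q1-q3) ==")
  for (v in cohort_numeric_fields()) {
    by_g <- vapply(split(bundle$cohort[[v]], bundle$cohort$group), fmt_iqr,
                   character(1L))
    p <- bundle$group_comparison$p.value[bundle$group_comparison$variable == v]
    lines <- c(lines, sprintf("%-20s %s  p=%.3g", v,
                              paste(disp[names(by_g)], by_g,
                                    collapse = "  "), p))
  }
  lines <- c(lines, "", "== Composite score by PAH status ==",
             paste("          ", paste("Score =", 0:3, collapse = "  ")))
  for (g in rownames(bundle$distribution$counts))
    lines <- c(lines, paste(disp[[g]],
                            paste(bundle$distribution$counts[g, ],
                                  collapse = " ")))
  lines <- c(lines, sprintf("chi-squared for trend: %.1f (p %s)",
                            bundle$trend$statistic,
                            format.pval(bundle$trend$p.value, digits = 2)))
  panel <- function(name, m) {
    c(sprintf("-- %s (cutoff %.4g, AUC %.3f [%.3f-%.3f]) --", name,
              m$cutoff, m$auc[["auc"]], m$auc[["lower"]], m$auc[["upper"]]),
      utils::capture.output(print(m$accuracy)))
  }
  lines <- c(lines, "", "== Single-marker accuracy ==")
  for (mk in names(bundle$markers))
    lines <- c(lines, panel(mk, bundle$markers[[mk]]))
  lines <- c(lines, "", "== Composite score (positive at >= 3 points) ==",
             sprintf("AUC %.3f [%.3f-%.3f]", bundle$composite$auc[["auc"]],
                     bundle$composite$auc[["lower"]],
                     bundle$composite$auc[["upper"]]),
             utils::capture.output(print(bundle$composite$accuracy)))
  lines
}

#' @export
print.cpet_report <- function(x, ...) {
  cat(render_tables(x), sep = "\n")
  invisible(x)
}
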