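#' Two-by-two confusion counts
#'
#' @param tp,fp,fn,tn Nonnegative integer counts (true/false positives,
#'   false/true negatives). Metrics additionally require at least one
#'   diseased (`tp + fn >= 1`) and one non-diseased (`fp + tn >= 1`) subject.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (!all(is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  counts <- as.list(counts)
  structure(lapply(counts, as.integer), class = "two_by_two")
}

#' Dichotomise a marker at a cutoff
#'
#' Builds the confusion table of a continuous or ordinal marker against
#' disease status at a given cutoff. Positivity at the cutoff value itself
#' follows the marker's direction: `value <= cutoff` when low values indicate
#' disease, and `value >= cutoff` (or `value > cutoff` with `strict = TRUE`,
#' as for the VE/VCO2 slope rule) when high values do.
#'
#' @param values Numeric marker values, no missing entries.
#' @param diseased Logical disease status, same length.
#' @param cutoff The threshold.
#' @param orientation `"lower_is_diseased"` or `"higher_is_diseased"`.
#' @param strict For `higher_is_diseased`, use strict `>` instead of `>=`.
#' @return A [two_by_two()] object.
#' @export
confusion_at_threshold <- function(values, diseased, cutoff,
                                   orientation = c("lower_is_diseased",
                                                   "higher_is_diseased"),
                                   strict = FALSE) {
  orientation <- match.arg(orientation)
  if (length(values) != length(diseased))
    stop("values and diseased must have equal length", call. = FALSE)
  if (anyNA(values) || anyNA(diseased))
    stop("missing values are not allowed; exclude patients upstream",
         call. = FALSE)
  if (!any(diseased) || all(diseased))
    stop("both diseased and non-diseased subjects are required",
         call. = FALSE)
  positive <- switch(orientation,
    lower_is_diseased = values <= cutoff,
    higher_is_diseased = if (strict) values > cutoff else values >= cutoff)
  two_by_two(sum(positive & diseased), sum(positive & !diseased),
             sum(!positive & diseased), sum(!positive & !diseased))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from Beta quantiles: the lower bound is 0 when
#' `successes == 0` and the upper bound 1 when `successes == n`.
#'
#' @param successes,n Integer counts with `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' clopper_pearson(7, 8)    # 0.473 .. 0.997
#' clopper_pearson(111, 112)
clopper_pearson <- function(successes, n, level = 0.95) {
  if (!is.finite(successes) || !is.finite(n) || n < 1 ||
      successes < 0 || successes > n ||
      successes != round(successes) || n != round(n))
    stop("need integer counts with 0 <= successes <= n, n >= 1",
         call. = FALSE)
  stopifnot(level > 0, level < 1)
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

# z-quantile used throughout the log-method intervals (not 1.96 rounded)
z_quantile <- function(level) stats::qnorm(1 - (1 - level) / 2)

#' Likelihood ratios with log-method confidence intervals
#'
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`, with intervals
#' on the log scale: `se(log LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp -
#' 1/(fp+tn))` and analogously for LR- with `fn`, `tn`. A zero cell makes a
#' ratio infinite or zero and its interval undefined (`NA`); this is
#' signalled, not an error. With `correction = TRUE` the Haldane-Anscombe
#' +0.5 adjustment is applied to every cell first.
#'
#' @param tab A [two_by_two()] object.
#' @param level Confidence level, default 0.95.
#' @param correction Apply the +0.5 continuity correction (default `FALSE`).
#' @return A list with elements `lr_pos` and `lr_neg`, each
#'   `c(estimate, lower, upper)`.
#' @export
likelihood_ratios <- function(tab, level = 0.95, correction = FALSE) {
  stopifnot(inherits(tab, "two_by_two"))
  tp <- tab$tp; fp <- tab$fp; fn <- tab$fn; tn <- tab$tn
  if (tp + fn < 1 || fp + tn < 1)
    stop("need at least one diseased and one non-diseased subject",
         call. = FALSE)
  if (correction && any(c(tp, fp, fn, tn) == 0)) {
    tp <- tp + 0.5; fp <- fp + 0.5; fn <- fn + 0.5; tn <- tn + 0.5
  }
  nd <- tp + fn
  nh <- fp + tn
  sens <- tp / nd
  spec <- tn / nh
  z <- z_quantile(level)
  lr_one <- function(num, den, a, b) {
    # num/den are the two proportions; a, b the numerator cells of each
    est <- if (den == 0) (if (num == 0) NaN else Inf) else num / den
    if (a > 0 && b > 0 && is.finite(est) && est > 0) {
      se <- sqrt(1 / a - 1 / nd + 1 / b - 1 / nh)
      c(estimate = est, lower = est * exp(-z * se),
        upper = est * exp(z * se))
    } else {
      c(estimate = est, lower = NA_real_, upper = NA_real_)
    }
  }
  list(lr_pos = lr_one(sens, 1 - spec, tp, fp),
       lr_neg = lr_one(1 - sens, spec, fn, tn))
}

#' Prevalence-adjusted predictive values via Bayes' theorem
#'
#' Converts the stated pre-test prevalence to odds, multiplies by the
#' likelihood ratios, and converts post-test odds back to probabilities:
#' `PPV = odds * LR+ / (1 + odds * LR+)`, `NPV = 1 - odds * LR- /
#' (1 + odds * LR-)`. Confidence bounds are obtained by pushing the supplied
#' likelihood-ratio interval endpoints through the same transform.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @param prevalence Pre-test probability of disease, strictly in `(0, 1)`.
#' @param lr Optional result of [likelihood_ratios()]; when supplied, its
#'   intervals yield PPV/NPV bounds.
#' @return A list with `ppv` and `npv`, each `c(estimate, lower, upper)`
#'   (`NA` bounds when no likelihood-ratio intervals are available).
#' @export
predictive_values <- function(sensitivity, specificity, prevalence = 0.10,
                              lr = NULL) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  odds <- prevalence / (1 - prevalence)
  post_pos <- function(l) if (is.infinite(l)) 1 else odds * l / (1 + odds * l)
  lr_pos <- if (specificity == 1) Inf else sensitivity / (1 - specificity)
  lr_neg <- if (specificity == 0) NaN else (1 - sensitivity) / specificity
  ppv <- post_pos(lr_pos)
  npv <- 1 - post_pos(lr_neg)
  ppv_ci <- npv_ci <- c(NA_real_, NA_real_)
  if (!is.null(lr)) {
    if (all(is.finite(lr$lr_pos[c("lower", "upper")])))
      ppv_ci <- c(post_pos(lr$lr_pos[["lower"]]),
                  post_pos(lr$lr_pos[["upper"]]))
    if (all(is.finite(lr$lr_neg[c("lower", "upper")])))
      npv_ci <- c(1 - post_pos(lr$lr_neg[["upper"]]),
                  1 - post_pos(lr$lr_neg[["lower"]]))
  }
  list(ppv = c(estimate = ppv, lower = ppv_ci[1L], upper = ppv_ci[2L]),
       npv = c(estimate = npv, lower = npv_ci[1L], upper = npv_ci[2L]))
}

#' Empirical ROC curve
#'
#' Operating points at every distinct observed value plus sentinel endpoints,
#' so the curve always includes a `sens = 1` and a `sens = 0` point.
#' Positivity uses `<=` under `lower_is_diseased` and `>=` under
#' `higher_is_diseased` (the integer composite score is handled by the
#' latter).
#'
#' @inheritParams confusion_at_threshold
#' @return An object of class `roc_curve`: thresholds with per-threshold
#'   sensitivity and specificity, class sizes, and the raw data (used by
#'   [auc()] and [auc_ci()]).
#' @export
roc_curve <- function(values, diseased,
                      orientation = c("lower_is_diseased",
                                      "higher_is_diseased")) {
  orientation <- match.arg(orientation)
  if (length(values) != length(diseased))
    stop("values and diseased must have equal length", call. = FALSE)
  if (anyNA(values) || anyNA(diseased))
    stop("missing values are not allowed", call. = FALSE)
  if (!any(diseased) || all(diseased))
    stop("both classes must be present", call. = FALSE)
  if (length(unique(values)) < 2L)
    stop("need at least 2 distinct marker values", call. = FALSE)
  v <- sort(unique(values))
  thr <- if (orientation == "lower_is_diseased") c(-Inf, v) else c(v, Inf)
  nd <- sum(diseased)
  nh <- sum(!diseased)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- if (orientation == "lower_is_diseased") values <= thr[i]
           else values >= thr[i]
    sens[i] <- sum(pos & diseased) / nd
    spec[i] <- sum(!pos & !diseased) / nh
  }
  structure(list(orientation = orientation, thresholds = thr,
                 sensitivity = sens, specificity = spec,
                 n_diseased = nd, n_healthy = nh,
                 values = values, diseased = diseased),
            class = "roc_curve")
}

#' Area under the empirical ROC curve
#'
#' Computed as the Mann-Whitney probability that a diseased subject's marker
#' lies beyond a healthy subject's under the curve's orientation, counting
#' ties as 1/2 (midrank formulation).
#'
#' @param curve A [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  r <- rank(curve$values)
  nd <- curve$n_diseased
  nh <- curve$n_healthy
  a_high <- (sum(r[curve$diseased]) - nd * (nd + 1) / 2) / (nd * nh)
  if (curve$orientation == "higher_is_diseased") a_high else 1 - a_high
}

#' DeLong confidence interval for the AUC
#'
#' Placement-value (DeLong) variance estimator with a normal interval,
#' truncated to `[0, 1]`.
#'
#' @param curve A [roc_curve()].
#' @param level Confidence level, default 0.95.
#' @return Named vector `c(auc, lower, upper)`.
#' @export
auc_ci <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "roc_curve"))
  sgn <- if (curve$orientation == "higher_is_diseased") 1 else -1
  x <- sgn * curve$values[curve$diseased]   # diseased
  y <- sgn * curve$values[!curve$diseased]  # healthy
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  a <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  se <- sqrt(stats::var(v10) / length(x) + stats::var(v01) / length(y))
  z <- z_quantile(level)
  c(auc = a, lower = max(0, a - z * se), upper = min(1, a + z * se))
}

#' Youden-optimal threshold
#'
#' Selects the operating point maximising the Youden index
#' `J = sensitivity + specificity - 1`. Ties are broken toward higher
#' specificity, then toward the least extreme threshold (closest to the
#' pooled sample median), then toward the first in threshold order.
#'
#' @param curve A [roc_curve()].
#' @return A list: `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youden_optimal <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  cand <- which(j >= max(j) - 1e-12)
  cand <- cand[curve$specificity[cand] >=
                 max(curve$specificity[cand]) - 1e-12]
  if (length(cand) > 1L) {
    med <- stats::median(curve$values)
    dist <- abs(curve$thresholds[cand] - med)
    dist[!is.finite(curve$thresholds[cand])] <- Inf
    cand <- cand[order(dist)][1L]
  }
  i <- cand[1L]
  list(threshold = curve$thresholds[i], J = j[i],
       sensitivity = curve$sensitivity[i], specificity = curve$specificity[i])
}

#' Full accuracy panel for a dichotomised marker
#'
#' Sensitivity and specificity with exact Clopper-Pearson intervals,
#' likelihood ratios with log-method intervals, and prevalence-adjusted
#' predictive values with intervals obtained by transforming the
#' likelihood-ratio bounds.
#'
#' @param tab A [two_by_two()] object.
#' @param prevalence Pre-test prevalence used for PPV/NPV, default 0.10.
#' @param level Confidence level, default 0.95.
#' @return An object of class `accuracy_report` (a list of named
#'   `c(estimate, lower, upper)` vectors plus the inputs).
#' @export
accuracy_report <- function(tab, prevalence = 0.10, level = 0.95) {
  stopifnot(inherits(tab, "two_by_two"))
  nd <- tab$tp + tab$fn
  nh <- tab$fp + tab$tn
  if (nd < 1 || nh < 1)
    stop("need at least one diseased and one non-diseased subject",
         call. = FALSE)
  sens_ci <- clopper_pearson(tab$tp, nd, level)
  spec_ci <- clopper_pearson(tab$tn, nh, level)
  lr <- likelihood_ratios(tab, level)
  pv <- predictive_values(tab$tp / nd, tab$tn / nh, prevalence, lr)
  structure(list(
    table = tab, prevalence = prevalence, level = level,
    sensitivity = c(estimate = tab$tp / nd, sens_ci),
    specificity = c(estimate = tab$tn / nh, spec_ci),
    lr_pos = lr$lr_pos, lr_neg = lr$lr_neg,
    ppv = pv$ppv, npv = pv$npv), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 3, ...) {
  pct <- function(v) sprintf("%.1f%% (%.1f-%.1f)", 100 * v[1L], 100 * v[2L],
                             100 * v[3L])
  num <- function(v) sprintf("%.*g (%.*g-%.*g)", digits, v[1L], digits,
                             v[2L], digits, v[3L])
  cat("Diagnostic accuracy (prevalence ", x$prevalence * 100, "%, ",
      x$level * 100, "% CI)\n", sep = "")
  cat("  sensitivity:", pct(x$sensitivity), "\n")
  cat("  specificity:", pct(x$specificity), "\n")
  cat("  LR+:", num(x$lr_pos), "  LR-:", num(x$lr_neg), "\n")
  cat("  PPV:", pct(x$ppv), "  NPV:", pct(x$npv), "\n")
  invisible(x)
}
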