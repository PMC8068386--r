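#' Kruskal-Wallis rank test with tie correction
#'
#' Computed from the rank formula: with midranks `R_j` summed per group,
#' `H = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)`, divided by the tie
#' correction `1 - sum(t^3 - t) / (N^3 - N)` over tie-group sizes `t`.
#' The p-value uses the chi-squared approximation with `k - 1` degrees of
#' freedom.
#'
#' @param groups Named list of numeric vectors, one per group; at least two
#'   groups with at least one observation each, and not all observations
#'   identical.
#' @return List with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  if (any(sizes < 1L))
    stop("every group needs at least one observation", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  n <- length(x)
  if (n < k + 1L)
    stop("too few observations for a rank test", call. = FALSE)
  if (length(unique(x)) == 1L)
    stop("degenerate data: all observations identical", call. = FALSE)
  r <- rank(x)
  g <- rep(seq_len(k), sizes)
  rj <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rj^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  list(statistic = h, df = k - 1L,
       p.value = stats::pchisq(h, k - 1L, lower.tail = FALSE))
}

#' Pearson chi-squared test of independence
#'
#' `sum((obs - exp)^2 / exp)` with expected counts from the product of the
#' margins; no continuity correction; `df = (r - 1)(c - 1)`.
#'
#' @param tab Count matrix, at least 2 x 2, with strictly positive margins.
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(!is.finite(tab)))
    stop("counts must be finite and nonnegative", call. = FALSE)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column margin", call. = FALSE)
  expected <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Cochran-Armitage chi-squared test for trend
#'
#' Tests a monotone trend in event proportions across ordered categories.
#' With scores `s_i`, events `r_i`, totals `n_i`, overall rate
#' `pbar = R / N`: `T = sum(s_i r_i) - (R / N) sum(s_i n_i)`,
#' `Var = pbar (1 - pbar) [sum(s_i^2 n_i) - (sum(s_i n_i))^2 / N]`, and the
#' statistic `T^2 / Var` is referred to chi-squared on 1 df. Unconditional
#' variant, no continuity correction. Invariant under affine rescaling of
#' the scores.
#'
#' @param events Event count per ordered category.
#' @param totals Category totals, `0 <= events <= totals`.
#' @param scores Category scores, default `0, 1, 2, ...`.
#' @return List with `statistic`, `df` (1), `p.value`.
#' @export
#' @examples
#' chi2_trend(c(1, 0, 0, 7), c(61, 34, 17, 8))  # statistic 34.3
chi2_trend <- function(events, totals, scores = seq_along(events) - 1) {
  stopifnot(length(events) == length(totals),
            length(scores) == length(events))
  if (any(events < 0) || any(events > totals))
    stop("need 0 <= events <= totals in every category", call. = FALSE)
  if (sum(totals > 0) < 2L)
    stop("need at least two non-empty categories", call. = FALSE)
  bign <- sum(totals)
  bigr <- sum(events)
  if (bigr == 0 || bigr == bign)
    stop("need at least one event and one non-event overall", call. = FALSE)
  pbar <- bigr / bign
  tstat <- sum(scores * events) - pbar * sum(scores * totals)
  v <- pbar * (1 - pbar) * (sum(scores^2 * totals) -
                              sum(scores * totals)^2 / bign)
  if (v <= 0)
    stop("degenerate data: zero trend variance", call. = FALSE)
  stat <- tstat^2 / v
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Pairwise Mann-Whitney comparisons with Bonferroni adjustment
#'
#' Post-hoc follow-up to a significant Kruskal-Wallis result: every pair of
#' groups is compared by [stats::wilcox.test()] and p-values are
#' Bonferroni-adjusted.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level applied to adjusted p-values.
#' @return Data frame: `group1`, `group2`, `p.value`, `p.adjusted`,
#'   `significant`.
#' @export
pairwise_mann_whitney <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  pairs <- utils::combn(names(groups), 2L)
  p <- apply(pairs, 2L, function(pr)
    suppressWarnings(stats::wilcox.test(groups[[pr[1L]]],
                                        groups[[pr[2L]]])$p.value))
  adj <- stats::p.adjust(p, method = "bonferroni")
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], p.value = p,
             p.adjusted = adj, significant = adj < alpha,
             stringsAsFactors = FALSE)
}

#' Group comparison table for a cohort
#'
#' Kruskal-Wallis comparison of every numeric variable across the cohort's
#' groups, with Bonferroni-adjusted pairwise Mann-Whitney flags where the
#' omnibus test is significant — the structure of a clinical "Table 1".
#'
#' @param cohort A cohort data frame.
#' @param vars Variables to compare; defaults to all numeric patient fields.
#' @param alpha Significance level, default 0.05 (two-tailed).
#' @return Data frame with one row per variable: `variable`, `statistic`,
#'   `df`, `p.value`, and `pairwise` (comma-separated significant pairs,
#'   empty when the omnibus test is not significant).
#' @export
compare_groups <- function(cohort, vars = cohort_numeric_fields(),
                           alpha = 0.05) {
  validate_cohort(cohort)
  out <- lapply(vars, function(v) {
    groups <- split(cohort[[v]], cohort$group)
    groups <- lapply(groups, function(g) g[!is.na(g)])
    groups <- groups[lengths(groups) > 0L]
    res <- tryCatch(kruskal_wallis(groups), error = function(e) NULL)
    if (is.null(res))
      return(data.frame(variable = v, statistic = NA_real_, df = NA_integer_,
                        p.value = NA_real_, pairwise = "",
                        stringsAsFactors = FALSE))
    flags <- ""
    if (res$p.value < alpha && length(groups) > 2L) {
      pw <- pairwise_mann_whitney(groups, alpha)
      sig <- pw[pw$significant, , drop = FALSE]
      flags <- paste(sig$group1, sig$group2, sep = " vs ", collapse = ", ")
    }
    data.frame(variable = v, statistic = res$statistic, df = res$df,
               p.value = res$p.value, pairwise = flags,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
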