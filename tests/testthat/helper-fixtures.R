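# Build a minimal valid cohort row; CPET fields overridable per patient.
make_patients <- function(n, group, peak_vo2, ve_vco2_slope, petco2_basal,
                          id_prefix = group) {
  data.frame(
    id = sprintf("%s-%03d", id_prefix, seq_len(n)),
    group = rep(group, n), sex = rep("F", n),
    age = 60, fvc_pct = 100, fev1_pct = 100, dlco_pct = 80, lvef_pct = 60,
    spap_mmhg = 30, peak_vo2 = peak_vo2, vt1_pct_peak_vo2 = 55,
    ve_vco2_slope = ve_vco2_slope, petco2_basal = petco2_basal,
    pulse_o2_peak_pct = 80, eqco2_basal = 38, duration_min = 9,
    workload_watts = 60, rer = 1.0, stringsAsFactors = FALSE)
}

# Cohort engineered to reproduce the published score-by-status contingency:
# CTD patients scoring (60, 34, 17, 1) across 0..3 and PAH patients (1,0,0,7).
# Representative marker values per score level under the default cutoffs.
table3_cohort <- function() {
  lvl <- list(`0` = c(18.4, 29.1, 29.2), `1` = c(12.5, 29.1, 29.2),
              `2` = c(12.5, 40.4, 29.2), `3` = c(12.5, 40.4, 25.0))
  ctd_n <- c(`0` = 60L, `1` = 34L, `2` = 17L, `3` = 1L)
  pah_n <- c(`0` = 1L, `1` = 0L, `2` = 0L, `3` = 7L)
  pieces <- list()
  for (s in names(lvl)) {
    v <- lvl[[s]]
    if (ctd_n[[s]] > 0L)
      pieces[[paste0("a", s)]] <-
        make_patients(ctd_n[[s]], "CTD", v[1], v[2], v[3],
                      id_prefix = paste0("A", s))
    if (pah_n[[s]] > 0L)
      pieces[[paste0("b", s)]] <-
        make_patients(pah_n[[s]], "CTD_PAH", v[1], v[2], v[3],
                      id_prefix = paste0("B", s))
  }
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

# Exhaustive pairwise Mann-Whitney AUC: independent of the rank-based path.
auc_pairwise <- function(values, diseased, orientation) {
  d <- values[diseased]
  h <- values[!diseased]
  tot <- 0
  for (x in d) for (y in h) {
    beyond <- if (orientation == "higher_is_diseased") x > y else x < y
    tot <- tot + beyond + 0.5 * (x == y)
  }
  tot / (length(d) * length(h))
}

# Exhaustive Youden scan over every operating point of the empirical curve.
youden_scan <- function(values, diseased, orientation) {
  v <- sort(unique(values))
  thr <- if (orientation == "lower_is_diseased") c(-Inf, v) else c(v, Inf)
  best <- -Inf
  for (t in thr) {
    pos <- if (orientation == "lower_is_diseased") values <= t
           else values >= t
    j <- sum(pos & diseased) / sum(diseased) +
      sum(!pos & !diseased) / sum(!diseased) - 1
    if (j > best) best <- j
  }
  best
}

# Synthetic incremental-test gas-exchange series with a planted VE/VCO2
# slope and V-slope breakpoint. Times in seconds, 3 min rest then ramp.
ramp_series <- function(slope = 30, intercept = 3, noise_sd = 0,
                        vt1_vo2 = 1000, s1 = 0.9, s2 = 1.3,
                        n = 120, dt = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  time_s <- seq(0, by = dt, length.out = n)
  rest_end <- max(which(time_s < 180))
  loaded_start <- rest_end + 1L
  vo2 <- c(rep(300, rest_end),
           seq(300, 2000, length.out = n - rest_end))
  vco2 <- ifelse(vo2 <= vt1_vo2, s1 * vo2,
                 s1 * vt1_vo2 + s2 * (vo2 - vt1_vo2))
  ve <- intercept + slope * vco2 / 1000 +
    if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
  breath_series(time_s, pmax(ve, 0), vo2, vco2,
                rest_end = rest_end, loaded_start = loaded_start,
                buffering_end = n)
}
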