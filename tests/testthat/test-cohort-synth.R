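test_that("log-normal quartile fit matches the closed-form solution", {
  # degenerate IQR collapses to a point mass
  f <- fit_lognormal_quartiles(10, 10, 10)
  expect_equal(f$mu, log(10))
  expect_equal(f$sigma, 0)
  # published-style summary: median 18.4, IQR 15.1-21.8
  f <- fit_lognormal_quartiles(18.4, 15.1, 21.8)
  expect_equal(f$mu, log(18.4))
  expect_equal(f$sigma, (log(21.8) - log(15.1)) / (2 * qnorm(0.75)))
  expect_error(fit_lognormal_quartiles(10, 12, 15), "quartiles")
  expect_error(fit_lognormal_quartiles(10, -1, 15), "quartiles")
  expect_error(fit_lognormal_quartiles(10, 5, 8), "quartiles")
})

test_that("fitted distribution reproduces its quantile equations (Monte Carlo)", {
  f <- fit_lognormal_quartiles(18.4, 15.1, 21.8)
  set.seed(101)
  x <- rlnorm(1e6, f$mu, f$sigma)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  # the fit pins the median exactly; its quartiles are the least-squares
  # log-symmetric solution exp(mu -/+ z75*sigma), the targets themselves
  # only up to the family's symmetry (15.1/21.8 is slightly asymmetric)
  fitted_q <- exp(f$mu + c(-1, 1) * qnorm(0.75) * f$sigma)
  expect_lt(abs(q[2] - 18.4) / 18.4, 0.01)
  expect_lt(abs(q[1] - fitted_q[1]) / fitted_q[1], 0.01)
  expect_lt(abs(q[3] - fitted_q[2]) / fitted_q[2], 0.01)
  expect_lt(abs(fitted_q[1] - 15.1) / 15.1, 0.02)
  expect_lt(abs(fitted_q[2] - 21.8) / 21.8, 0.02)
})

test_that("default synthetic cohort has the study's group structure", {
  cohort <- generate_cohort(seed = 11)
  expect_equal(nrow(cohort), 131L)
  expect_equal(as.vector(table(cohort$group)[cohort_groups()]),
               c(112L, 8L, 11L))
  expect_silent(validate_cohort(cohort))
  # all physiologic values positive
  for (v in c("peak_vo2", "ve_vco2_slope", "petco2_basal"))
    expect_true(all(cohort[[v]] > 0))
})

test_that("generation is deterministic in the seed and empty specs give an empty cohort", {
  expect_identical(generate_cohort(seed = 5), generate_cohort(seed = 5))
  expect_false(identical(generate_cohort(seed = 5)$age,
                         generate_cohort(seed = 6)$age))
  specs <- default_group_specs()
  for (g in names(specs)) specs[[g]]$n <- 0L
  expect_equal(nrow(generate_cohort(specs, seed = 1)), 0L)
})

test_that("Gaussian copula induces the requested dependence and rejects bad matrices", {
  specs <- default_group_specs()
  rc <- matrix(c(1, 0.8, 0.8, 1), 2,
               dimnames = list(c("peak_vo2", "workload_watts"),
                               c("peak_vo2", "workload_watts")))
  specs$CTD <- group_spec("CTD", 4000L, specs$CTD$vars,
                          specs$CTD$sex_prop_m, rank_cor = rc)
  cohort <- generate_cohort(specs, seed = 21)
  a <- cohort[cohort$group == "CTD", ]
  expect_gt(cor(a$peak_vo2, a$workload_watts, method = "spearman"), 0.7)
  # uncorrelated variables stay near-independent
  expect_lt(abs(cor(a$peak_vo2, a$age, method = "spearman")), 0.1)
  bad <- matrix(c(1, 0.9, -0.9, 1), 2)  # asymmetric
  dimnames(bad) <- dimnames(rc)
  expect_error(group_spec("CTD", 10L, specs$CTD$vars, 0.1, rank_cor = bad),
               "symmetric")
  notpsd <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  nm <- c("peak_vo2", "workload_watts", "age")
  dimnames(notpsd) <- list(nm, nm)
  expect_error(group_spec("CTD", 10L, specs$CTD$vars, 0.1,
                          rank_cor = notpsd), "semi-definite")
})

test_that("missingness switch nulls CPET fields at roughly the requested rate", {
  specs <- default_group_specs()
  specs$CTD$n <- 2000L
  specs$CTD_PAH$n <- 0L
  specs$PH_OTHER$n <- 0L
  cohort <- generate_cohort(specs, seed = 31, missing_rate = 0.2)
  rate <- mean(is.na(cohort$peak_vo2))
  expect_gt(rate, 0.15)
  expect_lt(rate, 0.25)
  expect_true(all(!is.na(cohort$age)))  # non-CPET fields untouched
})

test_that("cohort CSV round-trips and malformed files give row-level errors", {
  cohort <- generate_cohort(seed = 41, missing_rate = 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back, cohort, tolerance = 1e-12)

  bad <- cohort
  bad$group <- as.character(bad$group)
  bad$group[3] <- "PAH-CTD"
  path2 <- withr::local_tempfile(fileext = ".csv")
  # bypass write validation to produce a corrupt file
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_cohort(path2), "row 3.*PAH-CTD")

  bad2 <- utils::read.csv(path, colClasses = "character")
  bad2$peak_vo2[5] <- "twelve"
  utils::write.csv(bad2, path2, row.names = FALSE)
  expect_error(read_cohort(path2), "row 5.*twelve.*peak_vo2")

  # header-only file reads as an empty cohort
  writeLines(paste(names(cohort), collapse = ","), path2)
  expect_equal(nrow(read_cohort(path2)), 0L)
})
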