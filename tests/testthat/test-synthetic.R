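test_that("generation is byte-identical under a fixed seed", {
  sch <- test_schema()
  plr <- plr_spec("CHF", n_records = 300, seed = 11)
  a <- generate_cohort(sch, plr)
  b <- generate_cohort(sch, plr)
  expect_identical(a, b)
  # and the global RNG stream is untouched
  withr::with_seed(99, x1 <- stats::runif(1))
  withr::with_seed(99, {
    invisible(generate_cohort(sch, plr_spec("CHF", n_records = 50, seed = 5)))
    x2 <- stats::runif(1)
  })
  expect_identical(x1, x2)
})

test_that("disturbances are centred and the propensity is a proper probability", {
  sch <- test_schema()
  n <- 10000
  coh <- generate_cohort(sch, plr_spec("CHF", n_records = n, seed = 21,
                                       outcome_link = "identity"))
  expect_true(all(coh$.m0 > 0 & coh$.m0 < 1))
  expect_true(all(coh$CHF %in% c(0L, 1L)))
  # E[U] = 0 within 4 standard errors; E[V] = 0 likewise
  expect_lt(abs(mean(coh$.u)), 4 * stats::sd(coh$.u) / sqrt(n))
  se_v <- sqrt(mean(coh$.m0 * (1 - coh$.m0)) / n)
  expect_lt(abs(mean(coh$.v)), 4 * se_v)
  # linear-probability link: U = Y - E[Y|W,X] is centred by construction
  coh2 <- generate_cohort(sch, plr_spec("CHF", n_records = n, seed = 22,
                                        outcome_link = "linear_probability"))
  expect_lt(abs(mean(coh2$.u)), 4 * stats::sd(coh2$.u) / sqrt(n))
})

test_that("unknown treatment flag raises a schema error", {
  expect_error(generate_cohort(test_schema(), plr_spec("NotAFlag", n_records = 10)),
               class = "echodml_schema_error")
  # administrative variables cannot be the designated treatment
  expect_error(generate_cohort(test_schema(), plr_spec("Procedure", n_records = 10)),
               class = "echodml_schema_error")
})

test_that("null effect leaves no treatment contrast after stratifying on g0(X)", {
  # brute-force oracle: with theta0 = 0, the urgent rate among W=1 and W=0
  # must agree within every decile of the latent g0(X)
  sch <- test_schema()
  coh <- generate_cohort(sch, plr_spec("CHF", theta0 = 0, n_records = 10000,
                                       seed = 31))
  dec <- dplyr::ntile(coh$.g0, 10)
  diffs <- vars <- numeric(0)
  for (d in unique(dec)) {
    y1 <- coh$urgent[dec == d & coh$CHF == 1]
    y0 <- coh$urgent[dec == d & coh$CHF == 0]
    if (length(y1) >= 30 && length(y0) >= 30) {
      diffs <- c(diffs, mean(y1) - mean(y0))
      vars <- c(vars, stats::var(y1) / length(y1) + stats::var(y0) / length(y0))
    }
  }
  pooled <- sum(diffs / vars) / sum(1 / vars)
  expect_lt(abs(pooled), 4 * sqrt(1 / sum(1 / vars)))
})

test_that("prevalence calibration hits its target and is monotone", {
  sch <- test_schema()
  # symmetric null case: median of a centred normal is 0
  plr0 <- plr_spec("CHF", theta0 = 0, target_prevalence = 0.5, seed = 41,
                   g0_coef = data.frame(term = character(), term2 = character(),
                                        coef = numeric()),
                   m0_coef = data.frame(term = character(), term2 = character(),
                                        coef = numeric()))
  expect_lt(abs(calibrate_prevalence(plr0, sch)), 0.05)
  # target 0.2 reached within +/- 0.01 on regenerated data at n = 50,000
  plr <- plr_spec("CHF", target_prevalence = 0.2, n_records = 50000, seed = 42)
  coh <- generate_cohort(sch, plr)
  expect_gte(mean(coh$urgent), 0.19)
  expect_lte(mean(coh$urgent), 0.21)
  # monotonicity of the link: higher target, higher intercept
  c2 <- calibrate_prevalence(plr_spec("CHF", target_prevalence = 0.2, seed = 43), sch)
  c4 <- calibrate_prevalence(plr_spec("CHF", target_prevalence = 0.4, seed = 43), sch)
  expect_gt(c4, c2)
  # same ordering under the linear-probability link
  l2 <- calibrate_prevalence(plr_spec("CHF", target_prevalence = 0.2, seed = 43,
                                      outcome_link = "linear_probability"), sch)
  l4 <- calibrate_prevalence(plr_spec("CHF", target_prevalence = 0.4, seed = 43,
                                      outcome_link = "linear_probability"), sch)
  expect_gt(l4, l2)
})

test_that("removing the shared dependence makes the naive contrast unbiased", {
  sch <- test_schema()
  theta0 <- 0.5
  empty <- data.frame(term = character(), term2 = character(), coef = numeric())
  # confounded: m0 and g0 share referral-flag drivers -> naive contrast
  # overshoots theta0 (the default coefficient patterns are positively aligned)
  coh_c <- generate_cohort(sch, plr_spec("CHF", theta0 = theta0, seed = 51,
                                         n_records = 10000,
                                         outcome_link = "identity"))
  naive_c <- mean(coh_c$outcome[coh_c$CHF == 1]) - mean(coh_c$outcome[coh_c$CHF == 0])
  expect_gt(naive_c, theta0 + 0.2)
  # dependence removed: constant propensity -> naive contrast recovers theta0
  coh_u <- generate_cohort(sch, plr_spec("CHF", theta0 = theta0, seed = 52,
                                         n_records = 10000, m0_coef = empty,
                                         outcome_link = "identity"))
  naive_u <- mean(coh_u$outcome[coh_u$CHF == 1]) - mean(coh_u$outcome[coh_u$CHF == 0])
  se <- sqrt(stats::var(coh_u$outcome) * (1 / sum(coh_u$CHF) + 1 / sum(1 - coh_u$CHF)))
  expect_lt(abs(naive_u - theta0), 4 * se)
})

test_that("cohort files round-trip losslessly and validate on read", {
  sch <- test_schema()
  coh <- generate_cohort(sch, plr_spec("CHF", n_records = 200, seed = 61))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  # latent truth never leaks into the observable export
  raw <- readr::read_csv(path, show_col_types = FALSE)
  expect_false(any(grepl("^\\.", names(raw))))
  back <- read_cohort(path)
  obs <- setdiff(names(back), c(".row_id"))
  expect_equal(as.data.frame(lapply(back[, obs], as.vector)),
               as.data.frame(lapply(coh[, obs], as.vector)))
  expect_equal(schema_variables(attr(back, "schema")),
               schema_variables(sch))
  # explicit request keeps the latent columns
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path2, include_latent = TRUE)
  expect_true(".g0" %in% names(readr::read_csv(path2, show_col_types = FALSE)))
})

test_that("malformed cohort files are rejected with the offending column named", {
  sch <- test_schema()
  coh <- generate_cohort(sch, plr_spec("CHF", n_records = 50, seed = 71))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  # a comorbidity flag with value 2
  txt <- readr::read_csv(path, show_col_types = FALSE)
  txt$HTN[3] <- 2
  readr::write_csv(txt, path)
  expect_error(read_cohort(path), regexp = "HTN",
               class = "echodml_format_error")
  # a missing column
  txt$HTN <- NULL
  readr::write_csv(txt, path)
  expect_error(read_cohort(path), regexp = "HTN",
               class = "echodml_format_error")
  # an undeclared categorical level
  coh2 <- generate_cohort(sch, plr_spec("CHF", n_records = 50, seed = 72))
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh2, path3)
  txt <- readr::read_csv(path3, show_col_types = FALSE)
  txt$Procedure[1] <- "MRI"
  readr::write_csv(txt, path3)
  expect_error(read_cohort(path3), regexp = "Procedure",
               class = "echodml_format_error")
})

test_that("a written default-schema cohort parses back into 14/29/20 groups", {
  sch <- default_schema()
  coh <- generate_cohort(sch, plr_spec("Mets", n_records = 400, seed = 81))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  counts <- table(schema_variables(attr(back, "schema"))$group)
  expect_equal(as.integer(counts[c("administration", "comorbidity", "referral")]),
               c(14L, 29L, 20L))
  expect_equal(ncol(back) - sum(counts) - 1L,
               length(intersect(c("interval_days", "urgent"), names(back))))
})
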