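test_that("residual-on-residual regression matches hand arithmetic and an oracle", {
  # identity
  v <- c(0.3, -1.2, 0.7, 2.1)
  expect_equal(residual_regression(v, v), 1)
  # hand arithmetic: sum(v*y)/sum(v^2) = 12/6
  expect_equal(residual_regression(c(1, -1, 2), c(2, -2, 4)), 2)
  # brute-force grid minimization of the least-squares objective
  withr::with_seed(8, {
    v <- rnorm(50)
    y <- 1.3 * v + rnorm(50, 0, 0.5)
  })
  theta <- residual_regression(v, y)
  sse <- function(t) sum((y - t * v)^2)
  lo <- -5; hi <- 5
  for (pass in 1:6) {
    grid <- seq(lo, hi, length.out = 401)
    best <- grid[which.min(vapply(grid, sse, numeric(1)))]
    step <- (hi - lo) / 400
    lo <- best - step
    hi <- best + step
  }
  expect_equal(theta, best, tolerance = 1e-6)
  # degenerate treatment residuals
  expect_error(residual_regression(rep(0, 10), rnorm(10)),
               class = "echodml_degenerate_treatment")
})

test_that("cross-fitting partitions rows and is reproducible", {
  d <- test_design(400, seed = 23)
  plan <- crossfit_plan(5, 3, seed = 9)
  res <- crossfit_residuals(d, "CHF", learner = learner_spec("linear"), plan = plan)
  # every row appears exactly once per repetition
  expect_equal(nrow(res), 400 * 3)
  for (r in 1:3) {
    sub <- res[res$rep == r, ]
    expect_setequal(sub$id, d$id)
    expect_equal(sort(unique(sub$fold)), 1:5)
  }
  # identical plan, identical residuals
  res2 <- crossfit_residuals(d, "CHF", learner = learner_spec("linear"), plan = plan)
  expect_identical(res, res2)
})

test_that("a constant propensity yields centred treatment residuals", {
  empty <- data.frame(term = character(), term2 = character(), coef = numeric())
  sch <- test_schema()
  plr <- plr_spec("CHF", theta0 = 0.5, outcome_link = "identity",
                  n_records = 4000, seed = 29, m0_coef = empty,
                  m0_intercept = 0)  # m0(X) = 0.5 everywhere
  d <- encode_dummies(generate_cohort(sch, plr))
  res <- crossfit_residuals(d, "CHF", learner = learner_spec("linear"),
                            plan = crossfit_plan(5, 1, seed = 2))
  expect_lt(abs(mean(res$v_hat)), 4 / sqrt(4000))
  expect_lt(abs(mean(res$m_hat) - 0.5), 0.05)
})

test_that("a null outcome produces null outcome residuals", {
  d <- test_design(200, seed = 31)
  d$y <- rep(0, d$n)
  res <- crossfit_residuals(d, "CHF", learner = learner_spec("weighted_logistic"),
                            plan = crossfit_plan(4, 1, seed = 3))
  # single-class folds fall back to the constant predictor (mean 0)
  expect_true(all(res$y_tilde == 0))
  expect_gt(attr(res, "fallbacks"), 0)
})

test_that("inference satisfies its own identities and degeneracy guards", {
  d <- test_design(1500, seed = 37)
  res <- crossfit_residuals(d, "CHF", learner = learner_spec("linear"),
                            plan = crossfit_plan(5, 4, seed = 4))
  fit <- dml_inference(res)
  expect_equal(fit$statistic, fit$estimate / fit$std.error, tolerance = 1e-12)
  expect_true(fit$conf.low <= fit$estimate && fit$estimate <= fit$conf.high)
  expect_equal(fit$p.value, 2 * stats::pnorm(-abs(fit$statistic)))
  expect_equal(nrow(fit$reps), 4)
  # orthogonality sanity bound per repetition
  expect_true(all(abs(fit$reps$mean_v) < 5 / sqrt(fit$n)))
  # exact linear dependence triggers the minimum-variance flag
  withr::with_seed(5, v <- rnorm(100))
  fake <- tibble::tibble(rep = 1L, id = 1:100, fold = 1L, w = 0, y = 0,
                         m_hat = 0, l_hat = 0, v_hat = v, y_tilde = 2 * v)
  fit0 <- dml_inference(fake, treatment = "x")
  expect_true("min_variance" %in% fit0$flags)
  expect_equal(fit0$estimate, 2)
  # tidy/glance round out the broom surface
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(glance(fit)["n"], "n")
})

test_that("row permutation leaves estimates unchanged (fold keyed to ids)", {
  d <- test_design(600, seed = 41)
  perm <- withr::with_seed(6, sample(d$n))
  dp <- d
  dp$x <- d$x[perm, ]
  dp$y <- d$y[perm]
  dp$id <- d$id[perm]
  plan <- crossfit_plan(5, 2, seed = 7)
  f1 <- dml_inference(crossfit_residuals(d, "CHF", learner = learner_spec("linear"),
                                         plan = plan))
  f2 <- dml_inference(crossfit_residuals(dp, "CHF", learner = learner_spec("linear"),
                                         plan = plan))
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-12)
  expect_equal(f1$std.error, f2$std.error, tolerance = 1e-12)
})

test_that("estimate_effects returns one fit per treatment and survives failures", {
  d <- test_design(800, seed = 43)
  eff <- estimate_effects(d, "comorbidity", learner = learner_spec("linear"),
                          plan = crossfit_plan(3, 1, seed = 8))
  expect_s3_class(eff, "dml_effects")
  expect_equal(nrow(eff), 6)  # six comorbidity flags in the test schema
  expect_setequal(eff$treatment, names(test_schema()$comorbidity))
  expect_true(all(eff$group == "comorbidity"))
  expect_equal(eff$statistic, eff$estimate / eff$std.error, tolerance = 1e-10)
  # a degenerate treatment column is reported, not fatal
  d2 <- d
  d2$x$Tumor <- rep(0L, d2$n)
  eff2 <- suppressMessages(
    estimate_effects(d2, "comorbidity", learner = learner_spec("linear"),
                     plan = crossfit_plan(3, 1, seed = 8)))
  bad <- eff2[eff2$treatment == "Tumor", ]
  expect_true(is.na(bad$estimate))
  expect_false(is.na(bad$error))
  expect_equal(sum(!is.na(eff2$estimate)), 5)
})

test_that("treatments with under 10 positives are flagged unreliable", {
  d <- test_design(300, seed = 47)
  d$x$Tumor <- c(rep(1L, 5), rep(0L, d$n - 5))
  res <- crossfit_residuals(d, "Tumor", learner = learner_spec("linear"),
                            plan = crossfit_plan(3, 1, seed = 9))
  expect_false(attr(res, "reliable"))
  expect_false(dml_inference(res)$reliable)
})

test_that("the DML urgency score reduces to the outcome nuisance at zero effects", {
  d <- test_design(500, seed = 53, outcome_link = "latent_threshold")
  eff <- estimate_effects(d, "comorbidity", learner = learner_spec("weighted_logistic"),
                          plan = crossfit_plan(4, 1, seed = 11))
  eff0 <- eff
  eff0$estimate <- rep(0, nrow(eff0))
  plan <- crossfit_plan(4, 1, seed = 11)
  pred0 <- predict_urgency(d, eff0, learner = learner_spec("weighted_logistic"),
                           plan = plan)
  # recompute the bare outcome nuisance with the same folds and seeds
  covs <- d$meta$column[d$meta$group != "comorbidity"]
  folds <- echodml:::make_folds(as.numeric(d$y), d$id, 4, echodml:::derive_seed(11, 1))
  l_hat <- echodml:::oof_predict(echodml:::as_feature_matrix(d$x[, covs]),
                                 as.numeric(d$y), folds,
                                 learner_spec("weighted_logistic"),
                                 echodml:::derive_seed(11, 2001L))$pred
  expect_equal(pred0$score, l_hat, tolerance = 1e-12)
  expect_equal(pred0$label, as.integer(l_hat >= 0.5))
  # determinism of the full score
  predA <- predict_urgency(d, eff, learner = learner_spec("weighted_logistic"),
                           plan = plan)
  predB <- predict_urgency(d, eff, learner = learner_spec("weighted_logistic"),
                           plan = plan)
  expect_identical(predA, predB)
  # missing fits are refused
  effNA <- eff
  effNA$estimate[2] <- NA_real_
  expect_error(predict_urgency(d, effNA, learner = learner_spec("weighted_logistic"),
                               plan = plan), regexp = "missing fit")
})
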