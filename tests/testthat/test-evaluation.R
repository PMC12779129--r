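# independent confusion-matrix oracle, written against base table()
oracle_metrics <- function(truth, est) {
  tab <- table(factor(truth, c(0, 1)), factor(est, c(0, 1)))
  tp <- tab["1", "1"]; fp <- tab["0", "1"]; fn <- tab["1", "0"]
  acc <- 100 * sum(diag(tab)) / sum(tab)
  prec <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

test_that("classification metrics match closed forms and the oracle", {
  # perfect predictions
  m <- classification_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 100, precision = 100, recall = 100, f1 = 100))
  # direct formula arithmetic: TP=30 FP=10 FN=70 TN=890
  truth <- c(rep(1, 100), rep(0, 900))
  est <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 890))
  m <- classification_metrics(truth, est)
  expect_equal(m$precision, 75)
  expect_equal(m$recall, 30)
  expect_equal(m$f1, 42.857, tolerance = 1e-4)
  # all-negative predictions at prevalence p
  p <- 0.2
  truth <- c(rep(1, 200), rep(0, 800))
  m <- classification_metrics(truth, rep(0, 1000))
  expect_equal(m$accuracy, 100 * (1 - p))
  expect_equal(m$recall, 0)
  expect_true(m$no_positive_flag)
  expect_error(classification_metrics(numeric(0), numeric(0)), "empty")
  # property: agreement with the independent oracle on random label pairs
  withr::with_seed(13, {
    for (i in 1:20) {
      truth <- rbinom(50, 1, runif(1, 0.1, 0.9))
      est <- rbinom(50, 1, runif(1, 0.1, 0.9))
      got <- classification_metrics(truth, est)
      want <- oracle_metrics(truth, est)
      expect_equal(unlist(got[c("accuracy", "precision", "recall", "f1")]),
                   want, tolerance = 1e-10)
    }
  })
})

test_that("the learner comparison has one row per learner with dispersions", {
  d <- test_design(400, seed = 59, outcome_link = "latent_threshold")
  learners <- list(nb = learner_spec("naive_bayes"),
                   wl = learner_spec("weighted_logistic"),
                   nb_again = learner_spec("naive_bayes"))
  tbl <- run_learner_comparison(d, learners, n_folds = 3, n_iterations = 2,
                                seed = 17)
  expect_equal(nrow(tbl), 3)
  expect_true(all(c("accuracy", "accuracy_sd", "precision", "precision_sd",
                    "recall", "recall_sd", "f1", "f1_sd") %in% names(tbl)))
  expect_true(all(tbl$accuracy >= 0 & tbl$accuracy <= 100))
  # identical specs see identical folds, hence identical rows
  expect_equal(as.numeric(tbl[tbl$learner == "nb", -1]),
               as.numeric(tbl[tbl$learner == "nb_again", -1]))
})

test_that("the benchmark adds exactly one DML row on shared folds", {
  d <- test_design(500, seed = 61, outcome_link = "latent_threshold")
  learners <- list(nb = learner_spec("naive_bayes"),
                   wl = learner_spec("weighted_logistic"))
  fits <- estimate_effects(d, "comorbidity", learner = learner_spec("linear"),
                           plan = crossfit_plan(3, 1, seed = 19))
  tbl <- run_dml_benchmark(d, learners, group = "comorbidity",
                           dml_learner = learner_spec("weighted_logistic"),
                           n_folds = 3, n_iterations = 2, seed = 19, fits = fits)
  expect_equal(nrow(tbl), length(learners) + 1)
  expect_equal(tbl$learner[nrow(tbl)], "double_machine_learning")
  expect_false(any(is.na(tbl$f1)))
})

test_that("effect reports filter, sort and keep the full inference table", {
  d <- test_design(600, seed = 67)
  eff <- estimate_effects(d, "comorbidity", learner = learner_spec("linear"),
                          plan = crossfit_plan(3, 1, seed = 23))
  rep_ <- build_effect_report(eff, alpha = 0.05)
  expect_equal(nrow(rep_$full), nrow(eff))
  expect_true(all(rep_$significant$p.value < 0.05))
  # sorted ascending by p within group
  expect_false(is.unsorted(rep_$full$p.value[rep_$full$group == "comorbidity"]))
  # significant == p < alpha, and group subtotals add up
  expect_equal(sum(rep_$full$significant), nrow(rep_$significant))
  gl <- glance(rep_)
  expect_equal(sum(gl$n_significant), nrow(rep_$significant))
  # all-null fits produce an empty significant view but a complete table
  effnull <- eff
  effnull$p.value <- rep(0.5, nrow(effnull))
  repnull <- build_effect_report(effnull)
  expect_equal(nrow(repnull$significant), 0)
  expect_equal(nrow(repnull$full), nrow(eff))
  # BH adjustment is an optional, clearly separate column
  repbh <- build_effect_report(eff, adjust = TRUE)
  expect_true("p_bh" %in% names(repbh$full))
  expect_true(all(repbh$full$p_bh >= repbh$full$p.value, na.rm = TRUE))
})

test_that("effect report files are stable under re-run", {
  d <- test_design(400, seed = 71)
  eff <- estimate_effects(d, "comorbidity", learner = learner_spec("linear"),
                          plan = crossfit_plan(3, 1, seed = 29))
  rep_ <- build_effect_report(eff)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_effect_report(rep_, dir1)
  write_effect_report(rep_, dir2)
  f1 <- file.path(dir1, "effects_combined.tsv")
  f2 <- file.path(dir2, "effects_combined.tsv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("plots build without evaluation errors", {
  d <- test_design(400, seed = 73)
  eff <- estimate_effects(d, "comorbidity", learner = learner_spec("linear"),
                          plan = crossfit_plan(3, 1, seed = 31))
  p1 <- ggplot2::autoplot(eff)
  expect_s3_class(p1, "ggplot")
  built <- ggplot2::ggplot_build(p1)
  expect_gt(nrow(built$data[[3]]), 0)
  tbl <- tibble::tibble(learner = c("a", "b"), f1 = c(40, 60),
                        f1_sd = c(1, 2))
  expect_s3_class(plot_benchmark(tbl), "ggplot")
})
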