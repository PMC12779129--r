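#' Binary classification metrics on the percentage scale
#'
#' Accuracy, precision, recall and F1 for the urgent (positive) class,
#' reported as percentages. Precision is defined as 0 (with a flag) when
#' there are no predicted positives; F1 is 0 when precision and recall are
#' both 0.
#'
#' @param truth Binary 0/1 vector of true labels.
#' @param estimate Binary 0/1 vector of predicted labels.
#' @return A one-row tibble with the four metrics, the confusion counts
#'   and a `no_positive_flag`.
#' @export
classification_metrics <- function(truth, estimate) {
  if (length(truth) == 0) rlang::abort("empty input")
  stopifnot(length(truth) == length(estimate))
  if (!is_binary01(truth) || !is_binary01(estimate)) {
    rlang::abort("labels must be binary 0/1")
  }
  tp <- sum(truth == 1 & estimate == 1)
  fp <- sum(truth == 0 & estimate == 1)
  fn <- sum(truth == 1 & estimate == 0)
  tn <- sum(truth == 0 & estimate == 0)
  accuracy <- 100 * (tp + tn) / length(truth)
  no_pos <- (tp + fp) == 0
  precision <- if (no_pos) 0 else 100 * tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 0 else 100 * tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn,
                 no_positive_flag = no_pos)
}

# one repeated-CV evaluation of a learner: pooled out-of-fold labels
cv_metrics_once <- function(x, y, spec, folds, threshold, seed_base) {
  oof <- oof_predict(x, y, folds, spec, seed_base)
  classification_metrics(y, as.integer(oof$pred >= threshold))
}

summarise_iterations <- function(per_iter) {
  metrics <- c("accuracy", "precision", "recall", "f1")
  out <- list()
  for (m in metrics) {
    out[[m]] <- mean(per_iter[[m]])
    out[[paste0(m, "_sd")]] <- stats::sd(per_iter[[m]])
  }
  tibble::as_tibble(out)
}

#' Repeated cross-validation comparison of learner families
#'
#' Evaluates each learner on the full design (all dummy columns as
#' features) under `n_iterations` independent `n_folds`-fold splits,
#' reporting the mean and standard deviation of accuracy, precision,
#' recall and F1 across iterations. All learners share identical fold
#' assignments within an iteration.
#'
#' @param design An `urgency_design` with a binary outcome.
#' @param learners List of `learner_spec`s (default: the seven compared
#'   families).
#' @param n_folds Folds per iteration (default 5).
#' @param n_iterations Independent repetitions (default 3).
#' @param seed Seed for the fold streams.
#' @param threshold Probability cutoff for the urgent label.
#' @return A tibble with one row per learner: metric means and `_sd`
#'   dispersions, in percent.
#' @export
run_learner_comparison <- function(design, learners = default_learners(),
                                   n_folds = 5L, n_iterations = 3L,
                                   seed = 1L, threshold = 0.5) {
  stopifnot(inherits(design, "urgency_design"), length(learners) >= 1)
  if (length(unique(design$y)) < 2) rlang::abort("outcome has a single class")
  y <- as.numeric(design$y)
  x <- as_feature_matrix(design$x)
  fold_sets <- lapply(seq_len(n_iterations), function(i)
    make_folds(y, design$id, n_folds, derive_seed(seed, i)))
  purrr::imap_dfr(learners, function(spec, idx) {
    name <- if (is.character(idx) && nzchar(idx)) idx else spec$family
    per_iter <- purrr::map_dfr(seq_len(n_iterations), function(i) {
      tryCatch(
        cv_metrics_once(x, y, spec, fold_sets[[i]], threshold,
                        derive_seed(seed, 500L + i)),
        error = function(e) tibble::tibble(accuracy = NA_real_,
                                           precision = NA_real_,
                                           recall = NA_real_, f1 = NA_real_,
                                           error = conditionMessage(e)))
    })
    dplyr::bind_cols(tibble::tibble(learner = name), summarise_iterations(per_iter))
  })
}

#' The seven learner families compared in the benchmark
#'
#' @param seed Seed shared by the specs.
#' @return Named list of `learner_spec`s.
#' @export
default_learners <- function(seed = 1L) {
  fams <- c("naive_bayes", "weighted_logistic", "deep_learning",
            "decision_tree", "random_forest", "gradient_boosting", "svm")
  stats::setNames(lapply(fams, function(f) learner_spec(f, seed = seed)), fams)
}

#' Benchmark direct learners against the double-machine-learning predictor
#'
#' Reproduces the structure of the prediction comparison: each baseline
#' learner predicts urgency directly from all design columns, while the
#' final row reassembles the urgency score from the fitted
#' double-machine-learning model ([predict_urgency()]). Within an
#' iteration every row of the table — baselines and DML alike — is
#' evaluated on byte-identical fold assignments.
#'
#' @param design An `urgency_design` with a binary outcome.
#' @param learners List of baseline `learner_spec`s.
#' @param group Treatment group whose fitted effects drive the DML row.
#' @param dml_learner `learner_spec` for the DML nuisances.
#' @param plan `crossfit_plan` used to estimate the effects.
#' @param n_folds,n_iterations,seed,threshold As in
#'   [run_learner_comparison()].
#' @param fits Optional precomputed `dml_effects` for `group` (skips
#'   re-estimation).
#' @return A tibble with `length(learners) + 1` rows; the last row is
#'   `"double_machine_learning"`.
#' @export
run_dml_benchmark <- function(design, learners = default_learners(),
                              group = "comorbidity",
                              dml_learner = learner_spec("gradient_boosting"),
                              plan = crossfit_plan(),
                              n_folds = 5L, n_iterations = 3L, seed = 1L,
                              threshold = 0.5, fits = NULL) {
  baseline <- run_learner_comparison(design, learners, n_folds = n_folds,
                                     n_iterations = n_iterations, seed = seed,
                                     threshold = threshold)
  if (is.null(fits)) {
    fits <- estimate_effects(design, group, learner = dml_learner, plan = plan)
  }
  y <- as.numeric(design$y)
  per_iter <- purrr::map_dfr(seq_len(n_iterations), function(i) {
    folds <- make_folds(y, design$id, n_folds, derive_seed(seed, i))
    pred <- predict_urgency(design, fits, learner = dml_learner,
                            plan = crossfit_plan(n_folds, 1L,
                                                 derive_seed(seed, 500L + i)),
                            threshold = threshold, folds = folds)
    classification_metrics(pred$truth, pred$label)
  })
  dml_row <- dplyr::bind_cols(tibble::tibble(learner = "double_machine_learning"),
                              summarise_iterations(per_iter))
  dplyr::bind_rows(baseline, dml_row)
}
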