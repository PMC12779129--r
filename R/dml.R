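#' Cross-fitting plan
#'
#' Describes the repeated K-fold scheme used to form out-of-fold nuisance
#' residuals: `n_folds`-fold splits repeated `n_repetitions` times, folds
#' stratified by the outcome so low-prevalence splits do not produce
#' single-class training folds. Fold membership is keyed to row ids, so
#' permuting the rows of a design (ids travelling with them) leaves every
#' row's fold — and therefore every residual — unchanged.
#'
#' @param n_folds Number of folds (default 5). `1` is an in-sample mode
#'   (train and evaluate on all rows) used for oracle checks against the
#'   classical partialling-out identity.
#' @param n_repetitions Number of repeated splits (default 10).
#' @param seed Master seed; per-repetition streams are derived from it.
#' @return An object of class `crossfit_plan`.
#' @export
crossfit_plan <- function(n_folds = 5L, n_repetitions = 10L, seed = 1L) {
  stopifnot(n_folds >= 1, n_repetitions >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "crossfit_plan")
}

#' @export
print.crossfit_plan <- function(x, ...) {
  cat(sprintf("<crossfit_plan> %d-fold x %d repetitions (seed %d)\n",
              x$n_folds, x$n_repetitions, x$seed))
  invisible(x)
}

# stratified fold assignment keyed to row ids (outcome-stratified when the
# outcome is binary)
make_folds <- function(y, id, n_folds, seed) {
  n <- length(y)
  if (n_folds <= 1L) return(rep(1L, n))
  ord <- order(id)
  yo <- y[ord]
  strata <- if (is_binary01(yo)) yo else rep(0, n)
  fold_sorted <- integer(n)
  withr::with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold_sorted[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds <- integer(n)
  folds[ord] <- fold_sorted
  folds
}

# out-of-fold conditional-mean predictions with constant fallback on
# degenerate training folds; returns list(pred, fallbacks)
oof_predict <- function(x, target, folds, spec, seed_base) {
  n <- nrow(x)
  pred <- numeric(n)
  fallbacks <- 0L
  for (f in sort(unique(folds))) {
    test <- folds == f
    train <- if (length(unique(folds)) == 1L) rep(TRUE, n) else !test
    sp <- spec
    sp$seed <- derive_seed(seed_base, f)
    fit <- tryCatch(
      fit_learner(sp, x[train, , drop = FALSE], target[train]),
      echodml_degenerate_fit = function(e) {
        fallbacks <<- fallbacks + 1L
        constant_learner(mean(target[train]), columns = colnames(x))
      })
    pred[test] <- predict_mean(fit, x[test, , drop = FALSE])
  }
  list(pred = pred, fallbacks = fallbacks)
}

#' Cross-fitted nuisance residuals for one treatment
#'
#' Implements the first two steps of the double-machine-learning recipe
#' for the partially linear model: for every repetition and fold, the
#' treatment `W` and the outcome `Y` are each predicted from the
#' covariates `X` by models trained on the complementary folds, and the
#' out-of-fold residuals `V = W - m(X)` and `Ytilde = Y - E[Y|X]` are
#' assembled for all rows.
#'
#' @param design An `urgency_design`.
#' @param treatment Treatment column name (binary design column), or a
#'   one-row tibble from [partition_treatments()].
#' @param covariates Character vector of covariate columns (ignored when
#'   `treatment` is a partition row).
#' @param learner A `learner_spec` used for both nuisance models.
#' @param plan A `crossfit_plan`.
#' @return A tibble with columns `rep`, `id`, `fold`, `w`, `y`, `m_hat`,
#'   `l_hat`, `v_hat`, `y_tilde`; attributes `n_pos` (treated rows),
#'   `reliable` (at least 10 treated rows) and `fallbacks`.
#' @export
crossfit_residuals <- function(design, treatment, covariates = NULL,
                               learner = learner_spec("gradient_boosting"),
                               plan = crossfit_plan()) {
  stopifnot(inherits(design, "urgency_design"), inherits(plan, "crossfit_plan"))
  if (is.data.frame(treatment)) {
    covariates <- treatment$covariates[[1]]
    treatment <- treatment$treatment[1]
  }
  if (!treatment %in% names(design$x)) {
    abort_schema(sprintf("treatment column '%s' not in design", treatment))
  }
  if (is.null(covariates)) {
    grp <- design$meta$group[design$meta$column == treatment]
    covariates <- design$meta$column[design$meta$group != grp]
  }
  w <- as.numeric(design$x[[treatment]])
  if (!is_binary01(w)) abort_schema("treatment column must be binary")
  y <- as.numeric(design$y)
  x <- as_feature_matrix(design$x[, covariates, drop = FALSE])
  out <- vector("list", plan$n_repetitions)
  fallbacks <- 0L
  for (r in seq_len(plan$n_repetitions)) {
    folds <- make_folds(y, design$id, plan$n_folds, derive_seed(plan$seed, r))
    m <- oof_predict(x, w, folds, learner, derive_seed(plan$seed, 1000L + r))
    l <- oof_predict(x, y, folds, learner, derive_seed(plan$seed, 2000L + r))
    fallbacks <- fallbacks + m$fallbacks + l$fallbacks
    out[[r]] <- tibble::tibble(
      rep = r, id = design$id, fold = folds, w = w, y = y,
      m_hat = m$pred, l_hat = l$pred,
      v_hat = w - m$pred, y_tilde = y - l$pred
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "treatment") <- treatment
  attr(res, "n_pos") <- sum(w == 1)
  attr(res, "reliable") <- sum(w == 1) >= 10
  attr(res, "fallbacks") <- fallbacks
  res
}

#' Residual-on-residual regression
#'
#' The final step of the double-machine-learning recipe: the no-intercept
#' least-squares slope of the outcome residuals on the treatment
#' residuals, `theta = sum(V * Ytilde) / sum(V^2)`.
#'
#' @param w_residuals Treatment residuals `V`.
#' @param y_residuals Outcome residuals `Ytilde`.
#' @return The scalar effect estimate.
#' @export
residual_regression <- function(w_residuals, y_residuals) {
  stopifnot(length(w_residuals) == length(y_residuals), length(w_residuals) >= 2)
  denom <- sum(w_residuals^2)
  if (denom <= 1e-12) {
    rlang::abort("treatment residuals are (numerically) all zero",
                 class = "echodml_degenerate_treatment")
  }
  sum(w_residuals * y_residuals) / denom
}

# sandwich variance of the partialling-out score for one repetition
plr_se <- function(theta, v, ytl) {
  n <- length(v)
  num <- mean(v^2 * (ytl - theta * v)^2)
  den <- mean(v^2)^2
  sqrt(num / den / n)
}

#' Inference for a cross-fitted effect estimate
#'
#' Computes, per repetition, the residual-on-residual estimate and its
#' sandwich standard error for the Neyman-orthogonal partialling-out
#' score, then aggregates across repetitions by the median, with the
#' variance aggregated as `median(se_r^2 + (theta_r - theta)^2)` so that
#' split-to-split variability is reflected in the reported standard error
#' (the standard aggregation rule for repeated cross-fitting). The
#' t-value uses the standard normal reference and the confidence interval
#' is `theta +/- z[1-alpha/2] * se`.
#'
#' @param residuals Tibble from [crossfit_residuals()].
#' @param treatment Treatment label (defaults to the attribute carried by
#'   `residuals`).
#' @param group Optional group label carried into the fit.
#' @param level Confidence level (default 0.95).
#' @return An object of class `dml_fit`.
#' @export
dml_inference <- function(residuals, treatment = NULL, group = NA_character_,
                          level = 0.95) {
  treatment <- treatment %||% attr(residuals, "treatment")
  reps <- dplyr::group_by(residuals, .data$rep)
  reps <- dplyr::summarise(
    reps,
    theta = residual_regression(.data$v_hat, .data$y_tilde),
    se = plr_se(theta, .data$v_hat, .data$y_tilde),
    mean_v = mean(.data$v_hat),
    mean_v2 = mean(.data$v_hat^2),
    mean_y_tilde = mean(.data$y_tilde),
    .groups = "drop"
  )
  n <- length(unique(residuals$id))
  estimate <- stats::median(reps$theta)
  # median aggregation with the cross-fit dispersion correction: each
  # repetition's variance is augmented by that repetition's squared
  # deviation from the aggregated estimate, so the reported se accounts
  # for split-to-split variability (it reduces to se_1 for a single
  # repetition)
  se <- stats::median(sqrt(reps$se^2 + (reps$theta - estimate)^2))
  flags <- character(0)
  if (any(reps$se < 1e-10)) flags <- c(flags, "min_variance")
  if (n < 30) flags <- c(flags, "small_sample")
  se_safe <- max(se, .Machine$double.eps)
  statistic <- estimate / se_safe
  p.value <- 2 * stats::pnorm(-abs(statistic))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(treatment = treatment, group = group,
         estimate = estimate, std.error = se, statistic = statistic,
         p.value = p.value,
         conf.low = estimate - z * se, conf.high = estimate + z * se,
         n = n, n_pos = attr(residuals, "n_pos"),
         reliable = isTRUE(attr(residuals, "reliable")),
         fallbacks = attr(residuals, "fallbacks") %||% 0L,
         flags = flags, level = level,
         theta_mean = mean(reps$theta),
         reps = reps),
    class = "dml_fit"
  )
}

#' @export
print.dml_fit <- function(x, ...) {
  cat(sprintf("<dml_fit> %s: theta = %.4f (se %.4f), t = %.2f, p = %.3g\n",
              x$treatment, x$estimate, x$std.error, x$statistic, x$p.value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.dml_fit <- function(x, ...) {
  tibble::tibble(
    treatment = x$treatment, group = x$group, estimate = x$estimate,
    std.error = x$std.error, statistic = x$statistic, p.value = x$p.value,
    conf.low = x$conf.low, conf.high = x$conf.high,
    reliable = x$reliable
  )
}

#' @export
glance.dml_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_pos = x$n_pos, n_repetitions = nrow(x$reps),
    theta_mean = x$theta_mean, theta_median = x$estimate,
    max_abs_mean_v = max(abs(x$reps$mean_v)),
    max_abs_mean_y_tilde = max(abs(x$reps$mean_y_tilde)),
    fallbacks = x$fallbacks,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Estimate the effect of every treatment in a variable group
#'
#' Runs the full double-machine-learning estimator once per design column
#' of the chosen group: covariates are the columns of the other groups,
#' nuisances are cross-fitted with the given learner and plan, and the
#' residual-on-residual estimate is aggregated over repetitions. A failure
#' for one treatment is recorded in its row and does not abort the group.
#'
#' @inheritParams partition_treatments
#' @param learner A `learner_spec` for both nuisance models.
#' @param plan A `crossfit_plan`.
#' @param progress Emit a progress message per treatment.
#' @return A `dml_effects` tibble: one row per treatment with estimate,
#'   standard error, t-value, p-value, confidence bounds, reliability flag
#'   and the underlying `dml_fit` in the `fit` list-column.
#' @export
estimate_effects <- function(design, group,
                             learner = learner_spec("gradient_boosting"),
                             plan = crossfit_plan(),
                             include_same_group = FALSE,
                             progress = FALSE) {
  specs <- partition_treatments(design, group, include_same_group)
  rows <- purrr::map(seq_len(nrow(specs)), function(i) {
    trt <- specs$treatment[i]
    if (progress) rlang::inform(sprintf("[%d/%d] %s", i, nrow(specs), trt))
    tryCatch({
      res <- crossfit_residuals(design, trt, specs$covariates[[i]], learner, plan)
      fit <- dml_inference(res, treatment = trt, group = group)
      dplyr::mutate(tidy(fit), n_pos = fit$n_pos, error = NA_character_,
                    fit = list(fit))
    }, error = function(e) {
      tibble::tibble(treatment = trt, group = group, estimate = NA_real_,
                     std.error = NA_real_, statistic = NA_real_,
                     p.value = NA_real_, conf.low = NA_real_,
                     conf.high = NA_real_, reliable = FALSE, n_pos = NA_integer_,
                     error = conditionMessage(e), fit = list(NULL))
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dml_effects", class(out))
  attr(out, "group") <- group
  attr(out, "plan") <- plan
  attr(out, "learner") <- learner
  out
}

#' @export
tidy.dml_effects <- function(x, ...) {
  out <- dplyr::select(tibble::as_tibble(x), -dplyr::any_of(c("fit", "error")))
  out
}

#' @export
glance.dml_effects <- function(x, ...) {
  tibble::tibble(
    group = attr(x, "group"),
    n_treatments = nrow(x),
    n_significant = sum(x$p.value < 0.05, na.rm = TRUE),
    n_unreliable = sum(!x$reliable, na.rm = TRUE),
    n_failed = sum(!is.na(x$error))
  )
}

#' Predict urgency from the fitted double-machine-learning model
#'
#' Reassembles a per-row urgency score from the cross-fitted pieces:
#' `score = E[Y|X] + sum_w theta_w * (W_w - m_w(X))`, with every component
#' predicted out-of-fold, so no row is scored by a model that saw it. With
#' all effects zero the score reduces to the thresholded outcome nuisance.
#'
#' @param design An `urgency_design` with a binary outcome.
#' @param fits A `dml_effects` table for one treatment group.
#' @param learner A `learner_spec` for the nuisance predictions.
#' @param plan A `crossfit_plan`; scores are averaged over repetitions.
#' @param threshold Score cutoff for the urgent label (default 0.5).
#' @param folds Optional explicit fold assignment (single repetition),
#'   used to share splits with benchmark baselines.
#' @return A tibble with columns `id`, `score`, `label` and `truth`.
#' @export
predict_urgency <- function(design, fits,
                            learner = learner_spec("gradient_boosting"),
                            plan = crossfit_plan(),
                            threshold = 0.5, folds = NULL) {
  stopifnot(inherits(design, "urgency_design"))
  if (!inherits(fits, "dml_effects") && !is.data.frame(fits)) {
    rlang::abort("`fits` must be a dml_effects table")
  }
  if (any(is.na(fits$estimate))) {
    rlang::abort(sprintf("missing fit for treatment(s): %s",
                         paste(fits$treatment[is.na(fits$estimate)], collapse = ", ")))
  }
  group <- attr(fits, "group") %||% fits$group[1]
  covariates <- design$meta$column[design$meta$group != group]
  missing_trt <- setdiff(fits$treatment, names(design$x))
  if (length(missing_trt)) {
    abort_schema(sprintf("treatments not in design: %s",
                         paste(missing_trt, collapse = ", ")))
  }
  y <- as.numeric(design$y)
  x <- as_feature_matrix(design$x[, covariates, drop = FALSE])
  theta <- stats::setNames(fits$estimate, fits$treatment)
  rep_folds <- if (!is.null(folds)) {
    list(folds)
  } else {
    lapply(seq_len(plan$n_repetitions), function(r)
      make_folds(y, design$id, plan$n_folds, derive_seed(plan$seed, r)))
  }
  score <- numeric(design$n)
  for (r in seq_along(rep_folds)) {
    fr <- rep_folds[[r]]
    l <- oof_predict(x, y, fr, learner, derive_seed(plan$seed, 2000L + r))
    s <- l$pred
    for (k in seq_along(theta)) {
      w <- as.numeric(design$x[[names(theta)[k]]])
      m <- oof_predict(x, w, fr, learner, derive_seed(plan$seed, 3000L + 100L * k + r))
      s <- s + theta[k] * (w - m$pred)
    }
    score <- score + s / length(rep_folds)
  }
  tibble::tibble(id = design$id, score = score,
                 label = as.integer(score >= threshold), truth = y)
}
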