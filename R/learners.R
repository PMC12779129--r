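#' Specify a nuisance / baseline learner
#'
#' A uniform adapter over the learner families compared for the nuisance
#' models of double machine learning and for the direct prediction
#' baselines: naive Bayes, class-weighted logistic regression, a small
#' feed-forward network (the "deep learning" stand-in), a decision tree,
#' a random forest, gradient-boosted trees and a probability-calibrated
#' linear support-vector machine. An additional `"linear"` family (plain
#' unregularized least squares) is provided for estimator validation —
#' with it, residual-on-residual regression reproduces the classical
#' partialling-out identity exactly.
#'
#' All families consume 0/1 dummy feature matrices and expose the
#' conditional mean `E[target | features]` through [predict_mean()].
#' Hyperparameter defaults are pinned in
#' `inst/extdata/default-config.yaml`; pass overrides through `...`.
#'
#' @param family One of `"naive_bayes"`, `"weighted_logistic"`,
#'   `"deep_learning"`, `"decision_tree"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"svm"`, `"linear"`.
#' @param ... Hyperparameter overrides (see [learner_defaults()]).
#' @param seed Seed for the stochastic families; fixing it makes fits
#'   reproducible.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(family = c("naive_bayes", "weighted_logistic",
                                    "deep_learning", "decision_tree",
                                    "random_forest", "gradient_boosting",
                                    "svm", "linear"),
                         ..., seed = 1L) {
  family <- rlang::arg_match(family)
  params <- utils::modifyList(learner_defaults(family), rlang::list2(...))
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "learner_spec")
}

#' Pinned hyperparameter defaults per learner family
#'
#' @param family Learner family name.
#' @return Named list of default hyperparameters.
#' @export
learner_defaults <- function(family) {
  switch(family,
    naive_bayes = list(laplace = 1),
    weighted_logistic = list(),
    deep_learning = list(hidden = c(16L, 8L), epochs = 150L, lr = 0.01, l2 = 1e-4),
    decision_tree = list(max_depth = 6L, min_n = 20L),
    random_forest = list(n_trees = 100L, max_depth = 8L, min_n = 10L, mtry = NULL),
    gradient_boosting = list(n_trees = 150L, learn_rate = 0.1, max_depth = 2L,
                             min_n = 10L),
    svm = list(cost = 1, maxit = 200L),
    linear = list(),
    rlang::abort(sprintf("unknown learner family '%s'", family))
  )
}

#' @export
print.learner_spec <- function(x, ...) {
  cat(sprintf("<learner_spec> %s (seed %d)\n", x$family, x$seed))
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    x
  } else {
    as.matrix(as.data.frame(x))
  }
}

#' Fit a learner to a feature matrix and target
#'
#' @param spec A `learner_spec`.
#' @param x Feature matrix or tibble of 0/1 dummy columns.
#' @param y Target vector: binary 0/1 for the classification families, any
#'   numeric for the families that also support conditional-mean
#'   regression (`decision_tree`, `random_forest`, `gradient_boosting`,
#'   `deep_learning`, `linear`).
#' @return A `learner_fit` handle usable with [predict_mean()].
#' @export
fit_learner <- function(spec, x, y) {
  stopifnot(inherits(spec, "learner_spec"))
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  binary <- is_binary01(y)
  if (binary && length(unique(y)) < 2) {
    rlang::abort("target has a single class; fit is degenerate",
                 class = "echodml_degenerate_fit",
                 mean = mean(y))
  }
  needs_binary <- spec$family %in% c("naive_bayes", "weighted_logistic", "svm")
  if (needs_binary && !binary) {
    rlang::abort(sprintf("family '%s' requires a binary 0/1 target", spec$family))
  }
  p <- spec$params
  fit <- withr::with_seed(spec$seed, switch(
    spec$family,
    naive_bayes = nb_fit(x, y, laplace = p$laplace),
    weighted_logistic = wlogit_fit(x, y),
    deep_learning = mlp_fit(x, y, hidden = p$hidden, epochs = p$epochs,
                            lr = p$lr, l2 = p$l2, binary = binary),
    decision_tree = tree_grow(x, y, max_depth = p$max_depth, min_n = p$min_n),
    random_forest = forest_fit(x, y, n_trees = p$n_trees,
                               mtry = p$mtry %||% max(1L, floor(sqrt(ncol(x)))),
                               max_depth = p$max_depth, min_n = p$min_n),
    gradient_boosting = boost_fit(x, y, n_trees = p$n_trees,
                                  learn_rate = p$learn_rate,
                                  max_depth = p$max_depth, min_n = p$min_n,
                                  binary = binary),
    svm = svm_fit(x, y, cost = p$cost, maxit = p$maxit),
    linear = ols_fit(x, y)
  ))
  structure(list(spec = spec, fit = fit, columns = colnames(x), binary = binary),
            class = "learner_fit")
}

#' Constant-mean predictor
#'
#' Fallback used when a training fold contains a single outcome class.
#'
#' @param mean_value The constant conditional mean to predict.
#' @param columns Feature columns the handle nominally accepts.
#' @return A `learner_fit` handle.
#' @export
constant_learner <- function(mean_value, columns = NULL) {
  structure(list(spec = list(family = "constant"),
                 fit = list(mean = mean_value), columns = columns,
                 binary = mean_value >= 0 && mean_value <= 1),
            class = "learner_fit")
}

#' Predict conditional means from a fitted learner
#'
#' Returns the estimated `E[target | features]`. For binary targets the
#' values are clipped to `[0, 1]`; for continuous targets (and the
#' `"linear"` validation family) raw means are returned.
#'
#' @param object A `learner_fit` from [fit_learner()].
#' @param x Feature matrix or tibble with the training columns.
#' @return Numeric vector of conditional means.
#' @export
predict_mean <- function(object, x) {
  stopifnot(inherits(object, "learner_fit"))
  x <- as_feature_matrix(x)
  if (!is.null(object$columns)) {
    if (!setequal(colnames(x), object$columns)) {
      miss <- setdiff(object$columns, colnames(x))
      extra <- setdiff(colnames(x), object$columns)
      rlang::abort(sprintf(
        "feature columns do not match training columns (missing: %s; extra: %s)",
        paste(miss, collapse = ", "), paste(extra, collapse = ", ")),
        class = "echodml_column_mismatch")
    }
    x <- x[, object$columns, drop = FALSE]
  }
  family <- object$spec$family
  out <- switch(
    family,
    constant = rep(object$fit$mean, nrow(x)),
    naive_bayes = nb_predict(object$fit, x),
    weighted_logistic = wlogit_predict(object$fit, x),
    deep_learning = mlp_predict(object$fit, x),
    decision_tree = tree_predict(object$fit, x),
    random_forest = forest_predict(object$fit, x),
    gradient_boosting = boost_predict(object$fit, x),
    svm = svm_predict(object$fit, x),
    linear = ols_predict(object$fit, x)
  )
  if (family != "linear" && object$binary) out <- clip01(out)
  out
}

# --- family implementations ------------------------------------------------

# Bernoulli naive Bayes with Laplace smoothing
nb_fit <- function(x, y, laplace = 1) {
  if (!all(x %in% c(0, 1))) rlang::abort("naive_bayes requires 0/1 features")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  list(
    log_prior = log(c(n0, n1) / (n0 + n1)),
    lp1 = log((colSums(x[y == 1, , drop = FALSE]) + laplace) / (n1 + 2 * laplace)),
    lp0 = log((colSums(x[y == 0, , drop = FALSE]) + laplace) / (n0 + 2 * laplace))
  )
}

nb_predict <- function(fit, x) {
  ll1 <- fit$log_prior[2] + x %*% fit$lp1 + (1 - x) %*% log1p(-exp(fit$lp1))
  ll0 <- fit$log_prior[1] + x %*% fit$lp0 + (1 - x) %*% log1p(-exp(fit$lp0))
  as.numeric(1 / (1 + exp(ll0 - ll1)))
}

# logistic regression with class weights inversely proportional to frequency
wlogit_fit <- function(x, y) {
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  xm <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(stats::glm.fit(xm, y, weights = w,
                                         family = stats::binomial()))
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  list(coef = coef, weights_balanced = length(unique(w)) == 1)
}

wlogit_predict <- function(fit, x) {
  as.numeric(inv_logit(cbind(1, x) %*% fit$coef))
}

# unregularized least squares (validation family; also the linear
# probability baseline)
ols_fit <- function(x, y) {
  xm <- cbind(`(Intercept)` = 1, x)
  qr_ <- qr(xm)
  coef <- qr.coef(qr_, y)
  coef[is.na(coef)] <- 0
  list(coef = coef)
}

ols_predict <- function(fit, x) as.numeric(cbind(1, x) %*% fit$coef)

# linear squared-hinge SVM trained by quasi-Newton, Platt-scaled so the
# decision values become conditional class probabilities
svm_fit <- function(x, y, cost = 1, maxit = 200L) {
  n <- nrow(x); p <- ncol(x)
  s <- 2 * y - 1
  lambda <- 1 / (cost * n)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    slack <- pmax(0, 1 - s * (x %*% w + b))
    0.5 * lambda * sum(w^2) + mean(slack^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    f <- as.numeric(x %*% w + b)
    slack <- pmax(0, 1 - s * f)
    gf <- -2 * s * slack / n
    c(lambda * w + as.numeric(crossprod(x, gf)), sum(gf))
  }
  opt <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = maxit))
  w <- opt$par[seq_len(p)]; b <- opt$par[p + 1]
  f <- as.numeric(x %*% w + b)
  platt <- suppressWarnings(stats::glm.fit(cbind(1, f), y,
                                           family = stats::binomial()))
  list(w = w, b = b, platt = platt$coefficients)
}

svm_predict <- function(fit, x) {
  f <- as.numeric(x %*% fit$w + fit$b)
  as.numeric(inv_logit(fit$platt[1] + fit$platt[2] * f))
}
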