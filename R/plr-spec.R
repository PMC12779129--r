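#' Specify the partially linear data-generating process
#'
#' A `plr_spec` fixes the causal structure used by [generate_cohort()]:
#' a latent outcome score `Y* = W * theta0 + g0(X) + U` together with a
#' binary treatment drawn as `W ~ Bernoulli(m0(X))`, so that `W = m0(X) + V`
#' with `E[V | X] = 0`. `X` collects every comorbidity and
#' referral-diagnosis flag other than the designated treatment flag;
#' `theta0` is the treatment effect on the latent outcome scale and is the
#' quantity the double-machine-learning estimator targets.
#'
#' @param treatment Name of the schema flag (comorbidity or referral group)
#'   whose generation is replaced by the propensity model `m0`. Any
#'   dependency edges leaving this flag are dropped during generation so
#'   that `theta0` is the full effect of `W` (no mediated paths).
#' @param theta0 True treatment effect on the latent outcome scale.
#' @param g0_form `"linear"` (main effects only) or
#'   `"nonlinear_interactions"` (main effects plus pairwise interaction
#'   terms) for the outcome nuisance `g0`.
#' @param m0_form `"linear_logit"` or `"nonlinear_logit"` for the treatment
#'   propensity `m0` (logistic link in both cases).
#' @param outcome_link How the latent score becomes the recorded outcome:
#'   `"latent_threshold"` (urgent = 1 when the score exceeds 0; intercept
#'   calibrated to `target_prevalence`), `"linear_probability"` (urgent
#'   drawn Bernoulli with the clipped score as its mean), or `"identity"`
#'   (the continuous score itself is the outcome; used to validate the
#'   estimator where the partially linear model holds exactly).
#' @param outcome_noise_sd Standard deviation of the Gaussian disturbance
#'   `U` (ignored under `"linear_probability"`, where the Bernoulli draw is
#'   the disturbance).
#' @param target_prevalence Desired marginal fraction of urgent records for
#'   the binary links, in (0,1).
#' @param n_records Number of appointment records to generate.
#' @param seed Master seed; all randomness in generation flows from it.
#' @param g0_coef,m0_coef Optional coefficient tables (tibbles with columns
#'   `term`, `term2` (`NA` for main effects) and `coef`). Defaults are
#'   built from the schema by [default_nuisance_coefs()].
#' @param g0_intercept Outcome-model intercept; `NULL` means calibrate it
#'   with [calibrate_prevalence()] for the binary links (0 for identity).
#' @param m0_intercept Propensity intercept on the log-odds scale; `NULL`
#'   uses the logit of the treatment flag's marginal prevalence in the
#'   schema.
#'
#' @return An object of class `plr_spec`.
#' @export
plr_spec <- function(treatment,
                     theta0 = 0.5,
                     g0_form = c("linear", "nonlinear_interactions"),
                     m0_form = c("linear_logit", "nonlinear_logit"),
                     outcome_link = c("latent_threshold", "linear_probability", "identity"),
                     outcome_noise_sd = 1,
                     target_prevalence = 0.2,
                     n_records = 1000,
                     seed = 1,
                     g0_coef = NULL,
                     m0_coef = NULL,
                     g0_intercept = NULL,
                     m0_intercept = NULL) {
  g0_form <- rlang::arg_match(g0_form)
  m0_form <- rlang::arg_match(m0_form)
  outcome_link <- rlang::arg_match(outcome_link)
  stopifnot(is.character(treatment), length(treatment) == 1,
            is.numeric(theta0), length(theta0) == 1,
            outcome_noise_sd >= 0, n_records >= 1)
  if (outcome_link != "identity" &&
      (target_prevalence <= 0 || target_prevalence >= 1)) {
    rlang::abort("`target_prevalence` must lie in (0, 1).")
  }
  structure(
    list(
      treatment = treatment, theta0 = theta0,
      g0_form = g0_form, m0_form = m0_form,
      outcome_link = outcome_link,
      outcome_noise_sd = outcome_noise_sd,
      target_prevalence = target_prevalence,
      n_records = as.integer(n_records),
      seed = as.integer(seed),
      g0_coef = g0_coef, m0_coef = m0_coef,
      g0_intercept = g0_intercept, m0_intercept = m0_intercept
    ),
    class = "plr_spec"
  )
}

#' @export
print.plr_spec <- function(x, ...) {
  cat("<plr_spec>\n")
  cat(sprintf("  treatment: %s   theta0: %g\n", x$treatment, x$theta0))
  cat(sprintf("  g0: %s   m0: %s   link: %s\n", x$g0_form, x$m0_form, x$outcome_link))
  cat(sprintf("  n_records: %d   seed: %d\n", x$n_records, x$seed))
  invisible(x)
}

#' Default nuisance coefficient tables for a schema
#'
#' Builds deterministic coefficient tables for `g0` (outcome nuisance) and
#' `m0` (treatment propensity, log-odds scale). The tables are supported on
#' the flags of the *other* flag group than the treatment's (referral flags
#' for a comorbidity treatment and vice versa), so that with the default
#' covariate partition — which removes the treatment's whole group — every
#' confounder of the simulated treatment is observed and `theta0` is
#' identified. Supplying custom tables over same-group flags creates
#' unobserved confounding on purpose. Main-effect coefficients follow a
#' fixed alternating-sign, decaying pattern over the first ten flags;
#' nonlinear forms add pairwise interaction terms among the first four.
#' Propensity coefficients are scaled down so that `m0(X)` stays away from
#' 0 and 1.
#'
#' @param schema A `schema_config`.
#' @param form `"linear"`/`"linear_logit"` or the nonlinear variant.
#' @param treatment Flag excluded from the covariate set.
#' @param role `"g0"` or `"m0"`.
#' @return A tibble with columns `term`, `term2`, `coef`.
#' @export
default_nuisance_coefs <- function(schema, form, treatment, role = c("g0", "m0")) {
  role <- rlang::arg_match(role)
  flags <- if (treatment %in% names(schema$comorbidity)) {
    names(schema$referral)
  } else if (treatment %in% names(schema$referral)) {
    names(schema$comorbidity)
  } else {
    setdiff(schema_flags(schema), treatment)
  }
  pattern <- c(0.9, -0.7, 0.6, 0.5, -0.5, 0.4, -0.4, 0.3, 0.3, -0.3)
  k <- min(length(pattern), length(flags))
  scale <- if (role == "g0") 1 else 0.6
  main <- tibble::tibble(term = flags[seq_len(k)], term2 = NA_character_,
                         coef = pattern[seq_len(k)] * scale)
  nonlinear <- form %in% c("nonlinear_interactions", "nonlinear_logit")
  if (nonlinear && length(flags) >= 4) {
    pairs <- rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4))
    inter_coef <- if (role == "g0") c(1.0, -0.8, 0.7, 0.9) else c(0.8, -0.7, 0.6, 0.5)
    inter <- tibble::tibble(term = flags[pairs[, 1]], term2 = flags[pairs[, 2]],
                            coef = inter_coef)
    main <- dplyr::bind_rows(main, inter)
  }
  main
}

# evaluate a coefficient table on a 0/1 flag matrix; returns a length-n vector
eval_coef_table <- function(tbl, x) {
  out <- numeric(nrow(x))
  if (is.null(tbl) || nrow(tbl) == 0) return(out)
  missing <- setdiff(unique(c(tbl$term, tbl$term2[!is.na(tbl$term2)])), colnames(x))
  if (length(missing)) {
    abort_schema(sprintf("coefficient table refers to unknown columns: %s",
                         paste(missing, collapse = ", ")))
  }
  for (i in seq_len(nrow(tbl))) {
    v <- x[, tbl$term[i]]
    if (!is.na(tbl$term2[i])) v <- v * x[, tbl$term2[i]]
    out <- out + tbl$coef[i] * v
  }
  out
}
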