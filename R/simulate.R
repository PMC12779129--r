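#' Generate a synthetic appointment cohort with known causal structure
#'
#' Draws `n_records` appointment records from the schema's taxonomy with the
#' confounded partially linear structure fixed by the `plr_spec`:
#' comorbidity flags are drawn first, referral-diagnosis flags depend on
#' them through the schema's dependency edges, administrative variables
#' depend on the referral flags, the designated treatment flag is drawn
#' from the propensity `m0(X)` over the remaining flags, and the outcome is
#' built from the latent score `W * theta0 + g0(X) + U`. Latent truth
#' columns (`.g0`, `.m0`, `.u`, `.v`, `.ystar`) are kept alongside the
#' observables so that downstream estimators can be tested against the
#' ground truth; [write_cohort()] drops them unless asked not to.
#'
#' @param schema A `schema_config`.
#' @param plr A `plr_spec`; its `treatment` must name a comorbidity or
#'   referral flag of the schema.
#' @param latent Keep the latent truth columns (default `TRUE`).
#' @return A tibble with one row per appointment: `.row_id`, administrative
#'   variables (character), flag columns (integer 0/1), `interval_days` and
#'   `urgent` for the binary outcome links or `outcome` for the identity
#'   link, plus the latent columns. The schema and the spec (with the
#'   calibrated intercept filled in) are attached as attributes `schema`
#'   and `plr_spec`.
#' @export
generate_cohort <- function(schema, plr, latent = TRUE) {
  stopifnot(inherits(schema, "schema_config"), inherits(plr, "plr_spec"))
  if (!plr$treatment %in% schema_flags(schema)) {
    abort_schema(sprintf(
      "treatment '%s' is not a comorbidity or referral flag of the schema",
      plr$treatment))
  }
  plr <- fill_nuisance(schema, plr)
  intercept <- plr$g0_intercept
  if (is.null(intercept)) {
    intercept <- if (plr$outcome_link == "identity") 0 else calibrate_prevalence(plr, schema)
  }
  plr$g0_intercept <- intercept
  n <- plr$n_records
  out <- withr::with_seed(plr$seed, {
    parts <- sim_structural(schema, plr, n, admin = TRUE)
    u <- stats::rnorm(n, 0, plr$outcome_noise_sd)
    score <- plr$theta0 * parts$w + parts$g0x
    res <- switch(
      plr$outcome_link,
      identity = {
        list(outcome = score + intercept + u, u = u, ystar = score + intercept + u)
      },
      latent_threshold = {
        ystar <- score + intercept + u
        list(urgent = as.integer(ystar > 0), u = u, ystar = ystar)
      },
      linear_probability = {
        p <- clip01(score + intercept, eps = 0.01)
        urgent <- stats::rbinom(n, 1L, p)
        list(urgent = urgent, u = urgent - p, ystar = p)
      }
    )
    flags <- parts$flags
    flags[, plr$treatment] <- parts$w
    tbl <- tibble::as_tibble(as.data.frame(parts$admin, stringsAsFactors = FALSE))
    tbl <- dplyr::bind_cols(tibble::tibble(.row_id = seq_len(n)), tbl,
                            tibble::as_tibble(flags))
    if (!is.null(res$urgent)) {
      interval <- integer(n)
      n_urg <- sum(res$urgent)
      interval[res$urgent == 1] <- sample(0:2, n_urg, replace = TRUE)
      interval[res$urgent == 0] <- 3L + stats::rgeom(n - n_urg, 0.15)
      tbl$interval_days <- interval
      tbl$urgent <- res$urgent
    } else {
      tbl$outcome <- res$outcome
    }
    if (latent) {
      tbl$.g0 <- parts$g0x + intercept
      tbl$.m0 <- parts$m0x
      tbl$.u <- res$u
      tbl$.v <- parts$w - parts$m0x
      tbl$.ystar <- res$ystar
    }
    tbl
  })
  attr(out, "schema") <- schema
  attr(out, "plr_spec") <- plr
  out
}

# fill in default coefficient tables / propensity intercept
fill_nuisance <- function(schema, plr) {
  if (is.null(plr$g0_coef)) {
    plr$g0_coef <- default_nuisance_coefs(schema, plr$g0_form, plr$treatment, "g0")
  }
  if (is.null(plr$m0_coef)) {
    plr$m0_coef <- default_nuisance_coefs(schema, plr$m0_form, plr$treatment, "m0")
  }
  if (is.null(plr$m0_intercept)) {
    marg <- c(schema$comorbidity, schema$referral)[[plr$treatment]]
    plr$m0_intercept <- logit(marg)
  }
  plr
}

# structural draw shared by generation and calibration: flags, propensity,
# treatment and g0(X) without the outcome disturbance. Must be called inside
# an established RNG context.
sim_structural <- function(schema, plr, n, admin = FALSE) {
  w_name <- plr$treatment
  com_names <- names(schema$comorbidity)
  ref_names <- names(schema$referral)
  com <- matrix(0L, n, length(com_names), dimnames = list(NULL, com_names))
  for (nm in com_names) {
    if (nm == w_name) next
    com[, nm] <- stats::rbinom(n, 1L, schema$comorbidity[[nm]])
  }
  ecr <- schema$edges_comorbidity_referral
  ecr <- ecr[ecr$from != w_name, , drop = FALSE]
  ref <- matrix(0L, n, length(ref_names), dimnames = list(NULL, ref_names))
  for (nm in ref_names) {
    if (nm == w_name) next
    eta <- rep(logit(schema$referral[[nm]]), n)
    e <- ecr[ecr$to == nm, , drop = FALSE]
    for (i in seq_len(nrow(e))) eta <- eta + e$weight[i] * com[, e$from[i]]
    ref[, nm] <- stats::rbinom(n, 1L, inv_logit(eta))
  }
  admin_cols <- NULL
  if (admin) {
    era <- schema$edges_referral_administrative
    era <- era[era$from != w_name, , drop = FALSE]
    admin_cols <- lapply(names(schema$administrative), function(nm) {
      v <- schema$administrative[[nm]]
      logits <- matrix(log(v$probs), n, length(v$levels), byrow = TRUE)
      e <- era[era$to == nm, , drop = FALSE]
      for (i in seq_len(nrow(e))) {
        j <- match(e$level[i], v$levels)
        logits[, j] <- logits[, j] + e$weight[i] * ref[, e$from[i]]
      }
      sample_levels(logits, v$levels)
    })
    names(admin_cols) <- names(schema$administrative)
  }
  flags <- cbind(com, ref)
  x <- flags[, setdiff(colnames(flags), w_name), drop = FALSE]
  m0x <- inv_logit(plr$m0_intercept + eval_coef_table(plr$m0_coef, x))
  w <- stats::rbinom(n, 1L, m0x)
  g0x <- eval_coef_table(plr$g0_coef, x)
  list(flags = flags, admin = admin_cols, x = x, m0x = m0x, w = w, g0x = g0x)
}

#' Calibrate the outcome-model intercept to a target urgency prevalence
#'
#' Finds the intercept of the outcome model such that the simulated marginal
#' `P(urgent = 1)` matches `target_prevalence` within `tol` at `n_sim`
#' records. For the threshold link the intercept is read off the empirical
#' quantile of the latent score; for the linear-probability link a bounded
#' bisection is used. Both are deterministic given the spec's seed.
#'
#' @param plr A `plr_spec` with a binary `outcome_link`.
#' @param schema A `schema_config`.
#' @param n_sim Simulation size used for calibration.
#' @param tol Acceptable absolute deviation of the simulated prevalence.
#' @param max_iter Bisection step bound (linear-probability link).
#' @return The calibrated intercept (scalar).
#' @export
calibrate_prevalence <- function(plr, schema, n_sim = 50000, tol = 0.01,
                                 max_iter = 60) {
  stopifnot(inherits(plr, "plr_spec"), inherits(schema, "schema_config"))
  if (plr$outcome_link == "identity") {
    abort_calibration("the identity link has no prevalence to calibrate")
  }
  p_target <- plr$target_prevalence
  plr <- fill_nuisance(schema, plr)
  withr::with_seed(derive_seed(plr$seed, 104729L), {
    parts <- sim_structural(schema, plr, n_sim, admin = FALSE)
    if (plr$outcome_link == "latent_threshold") {
      base <- plr$theta0 * parts$w + parts$g0x +
        stats::rnorm(n_sim, 0, plr$outcome_noise_sd)
      intercept <- -stats::quantile(base, 1 - p_target, names = FALSE)
      if (abs(mean(base + intercept > 0) - p_target) > tol) {
        abort_calibration("prevalence unreachable under the threshold link")
      }
      intercept
    } else {
      score <- plr$theta0 * parts$w + parts$g0x
      f <- function(c) mean(clip01(score + c, eps = 0.01))
      lo <- -20; hi <- 20
      if (f(lo) > p_target || f(hi) < p_target) {
        abort_calibration("target prevalence unreachable under the linear-probability link")
      }
      for (i in seq_len(max_iter)) {
        mid <- (lo + hi) / 2
        if (f(mid) < p_target) lo <- mid else hi <- mid
        if (abs(f(mid) - p_target) <= tol / 2) break
      }
      mid <- (lo + hi) / 2
      if (abs(f(mid) - p_target) > tol) {
        abort_calibration("prevalence calibration did not converge")
      }
      mid
    }
  })
}

latent_cols <- function(x) grep("^\\.", names(x), value = TRUE)

#' Write / read a cohort as delimited text with a schema sidecar
#'
#' `write_cohort()` writes the observable columns as a comma-separated file
#' and the schema as a YAML sidecar at `<path>.schema.yaml`, so the
#' variable-to-group mapping survives the round trip. Latent truth columns
#' and the internal row index are dropped unless `include_latent = TRUE`.
#' `read_cohort()` restores the tibble, validates it against the sidecar
#' (or an explicitly supplied schema) and re-attaches the schema attribute.
#'
#' @param data A cohort tibble (from [generate_cohort()] or compatible).
#' @param path File path for the delimited file.
#' @param include_latent Also write the latent truth columns.
#' @param schema Optional `schema_config` overriding the attached/sidecar
#'   schema.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a validated tibble with the schema attached.
#' @export
write_cohort <- function(data, path, include_latent = FALSE, schema = NULL) {
  schema <- schema %||% attr(data, "schema")
  if (is.null(schema)) abort_format("no schema attached to the cohort; pass `schema`")
  drop <- if (include_latent) ".row_id" else latent_cols(data)
  out <- data[, setdiff(names(data), unique(c(drop, ".row_id"))), drop = FALSE]
  readr::write_csv(out, path)
  write_schema(schema, paste0(path, ".schema.yaml"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) abort_format(sprintf("cohort file not found: %s", path))
  if (is.null(schema)) {
    sidecar <- paste0(path, ".schema.yaml")
    if (!file.exists(sidecar)) {
      abort_format(sprintf("no schema sidecar found at %s; pass `schema`", sidecar))
    }
    schema <- read_schema(sidecar)
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  vars <- schema_variables(schema)
  outcome_cols <- intersect(c("interval_days", "urgent", "outcome"), names(tbl))
  if (length(outcome_cols) == 0) {
    abort_format("cohort has neither `interval_days`, `urgent` nor `outcome`")
  }
  missing <- setdiff(vars$variable, names(tbl))
  if (length(missing)) {
    abort_format(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(tbl), c(vars$variable, outcome_cols, latent_cols(tbl)))
  if (length(extra)) {
    abort_format(sprintf("unexpected columns: %s", paste(extra, collapse = ", ")))
  }
  for (nm in schema_flags(schema)) {
    if (!is_binary01(tbl[[nm]])) {
      abort_format(sprintf("flag column '%s' contains non-binary values", nm))
    }
    tbl[[nm]] <- as.integer(tbl[[nm]])
  }
  for (nm in names(schema$administrative)) {
    vals <- unique(tbl[[nm]])
    bad <- setdiff(vals, schema$administrative[[nm]]$levels)
    if (length(bad)) {
      abort_format(sprintf("variable '%s' has undeclared level(s): %s",
                           nm, paste(bad, collapse = ", ")))
    }
    tbl[[nm]] <- as.character(tbl[[nm]])
  }
  if ("urgent" %in% names(tbl)) {
    if (!is_binary01(tbl$urgent)) abort_format("column 'urgent' must be 0/1")
    tbl$urgent <- as.integer(tbl$urgent)
  }
  if ("interval_days" %in% names(tbl)) {
    if (any(tbl$interval_days < 0)) abort_format("column 'interval_days' must be non-negative")
    tbl$interval_days <- as.integer(tbl$interval_days)
  }
  tbl <- dplyr::bind_cols(tibble::tibble(.row_id = seq_len(nrow(tbl))),
                          tbl[, setdiff(names(tbl), ".row_id")])
  tbl <- tbl[, c(".row_id", vars$variable, outcome_cols,
                 setdiff(latent_cols(tbl), ".row_id")), drop = FALSE]
  attr(tbl, "schema") <- schema
  tbl
}
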