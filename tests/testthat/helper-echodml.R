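# Shared fixtures for the test suite: a compact schema (same three-group
# taxonomy as the default, fewer variables, so cross-fitting loops stay
# fast) and a Monte-Carlo harness for the estimator-validation studies.

test_schema <- function(confounding = 1) {
  admin <- list(
    Procedure = list(levels = c("TTE", "TEE", "Other"), probs = c(0.80, 0.08, 0.12)),
    Setting = list(levels = c("Outpatient", "Inpatient"), probs = c(0.70, 0.30)),
    AgeBand = list(levels = c("young", "mid", "old"), probs = c(0.30, 0.40, 0.30))
  )
  com <- c(CHF = 0.30, HTN = 0.45, DM = 0.20, Tumor = 0.12, Renal = 0.15,
           Anemia = 0.25)
  ref <- c(I = 0.35, J = 0.15, R = 0.30, Z = 0.20, E = 0.12, N = 0.08,
           C = 0.06, D = 0.10)
  ecr <- tibble::tribble(
    ~from, ~to, ~weight,
    "CHF", "I", 1.2,
    "HTN", "I", 0.6,
    "DM", "E", 1.2,
    "Tumor", "Z", 1.0,
    "Renal", "N", 1.5,
    "Anemia", "D", 1.8
  )
  era <- tibble::tribble(
    ~from, ~to, ~level, ~weight,
    "I", "Procedure", "TEE", 0.8,
    "I", "Setting", "Inpatient", 0.5,
    "Z", "Setting", "Inpatient", 0.9
  )
  ecr$weight <- ecr$weight * confounding
  era$weight <- era$weight * confounding
  schema_config(admin, com, ref, ecr, era)
}

# one validation cohort + design under the identity outcome link (the
# partially linear model holds exactly there)
test_design <- function(n, seed, theta0 = 0.5, g0_form = "linear",
                        m0_form = "linear_logit", treatment = "CHF",
                        schema = test_schema(), outcome_link = "identity") {
  plr <- plr_spec(treatment, theta0 = theta0, g0_form = g0_form,
                  m0_form = m0_form, outcome_link = outcome_link,
                  n_records = n, seed = seed)
  encode_dummies(generate_cohort(schema, plr))
}

# Monte-Carlo repetitions of the full estimator; returns one row per seed
# with the aggregated estimate, CI coverage of theta0, and the naive
# unadjusted treatment/outcome contrast for comparison
mc_dml <- function(n_seeds, n, theta0 = 0.5, g0_form = "linear",
                   m0_form = "linear_logit",
                   learner = learner_spec("linear"),
                   n_folds = 5, n_reps = 1, seed0 = 1000,
                   treatment = "CHF", schema = test_schema()) {
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    d <- test_design(n, seed = seed0 + s, theta0 = theta0, g0_form = g0_form,
                     m0_form = m0_form, treatment = treatment, schema = schema)
    plan <- crossfit_plan(n_folds, n_reps, seed = seed0 + s)
    res <- crossfit_residuals(d, treatment, learner = learner, plan = plan)
    fit <- dml_inference(res)
    w <- as.numeric(d$x[[treatment]])
    tibble::tibble(
      seed = s, theta = fit$estimate, se = fit$std.error,
      covered = fit$conf.low <= theta0 & theta0 <= fit$conf.high,
      naive = mean(d$y[w == 1]) - mean(d$y[w == 0])
    )
  })
}
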