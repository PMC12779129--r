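#' Load the pipeline configuration
#'
#' Reads the shipped default configuration (every tunable default of the
#' package in one YAML file) and merges a user file over it, recursively.
#'
#' @param path Optional user YAML configuration.
#' @return A nested list of configuration values.
#' @export
load_config <- function(path = NULL) {
  default_path <- system.file("extdata", "default-config.yaml", package = "echodml")
  cfg <- yaml::read_yaml(default_path)
  if (!is.null(path)) {
    if (!file.exists(path)) abort_format(sprintf("config file not found: %s", path))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg
}

config_schema <- function(cfg) default_schema(confounding = cfg$schema$confounding %||% 1)

config_plr <- function(cfg, seed = NULL, n = NULL) {
  p <- cfg$plr
  plr_spec(
    treatment = p$treatment, theta0 = p$theta0,
    g0_form = p$g0_form, m0_form = p$m0_form,
    outcome_link = p$outcome_link,
    outcome_noise_sd = p$outcome_noise_sd,
    target_prevalence = p$target_prevalence,
    n_records = n %||% p$n_records,
    seed = seed %||% p$seed
  )
}

config_plan <- function(cfg, seed = NULL) {
  crossfit_plan(n_folds = cfg$crossfit$n_folds,
                n_repetitions = cfg$crossfit$n_repetitions,
                seed = seed %||% cfg$crossfit$seed)
}

config_learner <- function(cfg, family = NULL, seed = 1L) {
  family <- family %||% cfg$learners$nuisance
  overrides <- cfg$learners[[family]] %||% list()
  rlang::exec(learner_spec, family = family, !!!overrides, seed = seed)
}
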