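#' Define the variable taxonomy of an appointment cohort
#'
#' A schema describes the three variable groups found in echocardiogram
#' scheduling data: multi-level *administrative* variables (procedure type,
#' referral routing, demographics, surgical context), binary *comorbidity*
#' flags, and binary *referral-diagnosis* flags. It also carries the
#' dependency edges that make the groups mutually informative: comorbidities
#' shift the log-odds of referral-diagnosis flags, and referral-diagnosis
#' flags shift the level log-odds of administrative variables. Those edges
#' are what create confounding between any designated treatment flag and the
#' urgency outcome in simulated cohorts.
#'
#' @param administrative Named list; each element is a list with character
#'   `levels` (at least two) and numeric `probs` summing to one.
#' @param comorbidity Named numeric vector of marginal prevalences in (0,1),
#'   one per binary comorbidity flag.
#' @param referral Named numeric vector of baseline prevalences in (0,1),
#'   one per binary referral-diagnosis flag (log-odds scale baselines are
#'   derived from these before dependency shifts are applied).
#' @param edges_comorbidity_referral Data frame with columns `from`
#'   (comorbidity flag), `to` (referral flag) and `weight` (log-odds shift
#'   applied when the comorbidity is present).
#' @param edges_referral_administrative Data frame with columns `from`
#'   (referral flag), `to` (administrative variable), `level` and `weight`
#'   (level log-odds shift applied when the flag is present).
#'
#' @return An object of class `schema_config`.
#' @seealso [default_schema()] for the shipped 14/29/20 taxonomy.
#' @export
schema_config <- function(administrative, comorbidity, referral,
                          edges_comorbidity_referral = NULL,
                          edges_referral_administrative = NULL) {
  if (length(administrative) == 0 || is.null(names(administrative))) {
    abort_schema("`administrative` must be a non-empty named list.")
  }
  for (nm in names(administrative)) {
    v <- administrative[[nm]]
    if (length(v$levels) < 2) {
      abort_schema(sprintf("administrative variable '%s' needs >= 2 levels", nm))
    }
    if (length(v$probs) != length(v$levels) || abs(sum(v$probs) - 1) > 1e-8) {
      abort_schema(sprintf("level frequencies of '%s' must match levels and sum to 1", nm))
    }
  }
  stopifnot(is.numeric(comorbidity), is.numeric(referral))
  if (any(comorbidity <= 0 | comorbidity >= 1) || any(referral <= 0 | referral >= 1)) {
    abort_schema("flag prevalences must lie strictly inside (0, 1)")
  }
  all_names <- c(names(administrative), names(comorbidity), names(referral))
  if (anyDuplicated(all_names)) {
    abort_schema("variable names must be unique across groups")
  }
  chk_edges <- function(e, cols) {
    if (is.null(e))

      return(tibble::tibble(!!!stats::setNames(rep(list(character()), length(cols) - 1), cols[-length(cols)]),
                            weight = numeric()))
    e <- tibble::as_tibble(e)
    stopifnot(all(cols %in% names(e)))
    e
  }
  ecr <- chk_edges(edges_comorbidity_referral, c("from", "to", "weight"))
  era <- chk_edges(edges_referral_administrative, c("from", "to", "level", "weight"))
  if (nrow(ecr) && !all(ecr$from %in% names(comorbidity) & ecr$to %in% names(referral))) {
    abort_schema("comorbidity->referral edges refer to unknown flags")
  }
  if (nrow(era) && !all(era$from %in% names(referral) & era$to %in% names(administrative))) {
    abort_schema("referral->administrative edges refer to unknown variables")
  }
  structure(
    list(
      administrative = administrative,
      comorbidity = comorbidity,
      referral = referral,
      edges_comorbidity_referral = ecr,
      edges_referral_administrative = era
    ),
    class = "schema_config"
  )
}

#' Default echocardiogram scheduling schema
#'
#' The shipped taxonomy mirrors the variable inventory of a large
#' echocardiography laboratory: 14 administrative variables (procedure
#' modality, referral routing, downstream-appointment context, demographics,
#' surgical timing), 29 Elixhauser-style comorbidity flags and 20
#' referral-diagnosis category flags. Marginal frequencies are plausible for
#' an outpatient echo population (e.g. transesophageal studies around 4% of
#' procedures); they are stated once here and are not fitted to any dataset.
#'
#' @param confounding Non-negative scalar scaling every dependency edge
#'   weight. `0` removes all cross-group dependence, which makes a naive
#'   treatment/outcome contrast unbiased in simulated cohorts.
#' @return A `schema_config`.
#' @export
default_schema <- function(confounding = 1) {
  stopifnot(is.numeric(confounding), confounding >= 0)
  admin <- list(
    Procedure = list(levels = c("TTE", "TEE", "Other"), probs = c(0.90, 0.04, 0.06)),
    ReferralType = list(levels = c("External", "Internal"), probs = c(0.25, 0.75)),
    ReferredFrom = list(levels = c("RST", "Other", "MCHS", "RSTH", "FLA", "ZZRST", "ARZ"),
                        probs = c(0.55, 0.10, 0.12, 0.08, 0.06, 0.05, 0.04)),
    ReferredBy = list(levels = c("CV", "IM", "Other", "OB", "Hosp", "PED", "FAM"),
                      probs = c(0.35, 0.20, 0.15, 0.05, 0.10, 0.05, 0.10)),
    ReferredType = list(levels = c("Outpatient", "Other"), probs = c(0.85, 0.15)),
    NextDepartment = list(levels = c("CV", "nonCV"), probs = c(0.45, 0.55)),
    NextLength = list(levels = c("0-1", "2-4", "5", "6", ">=7", "None"),
                      probs = c(0.15, 0.20, 0.08, 0.07, 0.30, 0.20)),
    MadeBeforeEcho = list(levels = c("N", "Y"), probs = c(0.60, 0.40)),
    GENDER = list(levels = c("Female", "Male"), probs = c(0.48, 0.52)),
    surgeryYN = list(levels = c("N", "Y"), probs = c(0.90, 0.10)),
    SurgeryYN_After = list(levels = c("N", "Y"), probs = c(0.85, 0.15)),
    diff_surgery_after = list(levels = c("0-1", "2-5", "6-15", ">=16", "none"),
                              probs = c(0.05, 0.08, 0.10, 0.12, 0.65)),
    Geo = list(levels = c("InState", "Town", "OutState"), probs = c(0.60, 0.25, 0.15)),
    AGE = list(levels = c("0-18", "19-55", "56-65", "66-75", ">75"),
               probs = c(0.05, 0.25, 0.25, 0.25, 0.20))
  )
  comorbidity <- c(
    CHF = 0.18, Valvular = 0.15, PHTN = 0.06, PVD = 0.09, HTN = 0.45,
    Paralysis = 0.02, NeuroOther = 0.07, Pulmonary = 0.14, DM = 0.16,
    DMcx = 0.06, Hypothyroid = 0.11, Renal = 0.12, Liver = 0.04, PUD = 0.02,
    HIV = 0.01, Lymphoma = 0.02, Mets = 0.04, Tumor = 0.08, Rheumatic = 0.04,
    Coagulopathy = 0.05, Obesity = 0.22, WeightLoss = 0.04, FluidsLytes = 0.12,
    BloodLoss = 0.02, Anemia = 0.15, Alcohol = 0.05, Drugs = 0.03,
    Psychoses = 0.02, Depression = 0.12
  )
  referral <- c(
    A = 0.01, B = 0.01, C = 0.03, D = 0.04, E = 0.08, F = 0.03, G = 0.01,
    H = 0.01, I = 0.35, J = 0.10, K = 0.03, L = 0.01, M = 0.05, N = 0.04,
    O = 0.01, P = 0.01, Q = 0.02, R = 0.30, S = 0.03, Z = 0.15
  )
  ecr <- tibble::tribble(
    ~from, ~to, ~weight,
    "CHF", "I", 1.2,
    "Valvular", "I", 1.0,
    "HTN", "I", 0.6,
    "PHTN", "J", 1.0,
    "Pulmonary", "J", 1.2,
    "Liver", "K", 2.0,
    "Alcohol", "K", 0.8,
    "Lymphoma", "C", 2.5,
    "Mets", "C", 1.0,
    "Mets", "Z", 1.2,
    "Tumor", "Z", 1.0,
    "WeightLoss", "Z", 0.5,
    "Renal", "N", 1.5,
    "DM", "E", 1.2,
    "DMcx", "E", 1.5,
    "Obesity", "E", 0.6,
    "Depression", "F", 1.8,
    "Psychoses", "F", 2.0,
    "Anemia", "D", 1.8,
    "Coagulopathy", "D", 1.2
  )
  era <- tibble::tribble(
    ~from, ~to, ~level, ~weight,
    "I", "Procedure", "TEE", 0.8,
    "I", "ReferredBy", "CV", 0.8,
    "I", "NextDepartment", "CV", 1.0,
    "J", "ReferredBy", "IM", 0.6,
    "C", "ReferredBy", "Other", 0.4,
    "O", "ReferredBy", "OB", 2.0,
    "P", "AGE", "0-18", 1.5,
    "Q", "AGE", "0-18", 1.0,
    "R", "ReferralType", "External", 0.5,
    "Z", "SurgeryYN_After", "Y", 1.2,
    "Z", "diff_surgery_after", "2-5", 0.8
  )
  ecr$weight <- ecr$weight * confounding
  era$weight <- era$weight * confounding
  schema_config(admin, comorbidity, referral, ecr, era)
}

#' Variable-to-group lookup for a schema
#'
#' @param schema A `schema_config`.
#' @return A tibble with columns `variable` and `group`
#'   (administration / comorbidity / referral).
#' @export
schema_variables <- function(schema) {
  stopifnot(inherits(schema, "schema_config"))
  tibble::tibble(
    variable = c(names(schema$administrative), names(schema$comorbidity),
                 names(schema$referral)),
    group = c(rep("administration", length(schema$administrative)),
              rep("comorbidity", length(schema$comorbidity)),
              rep("referral", length(schema$referral)))
  )
}

schema_flags <- function(schema) c(names(schema$comorbidity), names(schema$referral))

#' @export
print.schema_config <- function(x, ...) {
  cat("<schema_config>\n")
  cat(sprintf("  administrative variables: %d\n", length(x$administrative)))
  cat(sprintf("  comorbidity flags:        %d\n", length(x$comorbidity)))
  cat(sprintf("  referral-diagnosis flags: %d\n", length(x$referral)))
  cat(sprintf("  dependency edges:         %d + %d\n",
              nrow(x$edges_comorbidity_referral), nrow(x$edges_referral_administrative)))
  invisible(x)
}

# serialize / restore a schema as plain YAML (sidecar format for cohort files)
schema_to_list <- function(schema) {
  list(
    administrative = lapply(schema$administrative, function(v)
      list(levels = as.character(v$levels), probs = as.numeric(v$probs))),
    comorbidity = as.list(schema$comorbidity),
    referral = as.list(schema$referral),
    edges_comorbidity_referral = as.list(schema$edges_comorbidity_referral),
    edges_referral_administrative = as.list(schema$edges_referral_administrative)
  )
}

schema_from_list <- function(x) {
  unlist_num <- function(l) {
    out <- unlist(l)
    stats::setNames(as.numeric(out), names(out))
  }
  edges <- function(e) if (length(e$weight) == 0) NULL else tibble::as_tibble(lapply(e, unlist))
  schema_config(
    administrative = x$administrative,
    comorbidity = unlist_num(x$comorbidity),
    referral = unlist_num(x$referral),
    edges_comorbidity_referral = edges(x$edges_comorbidity_referral),
    edges_referral_administrative = edges(x$edges_referral_administrative)
  )
}

#' Write or read a schema as a YAML sidecar
#'
#' @param schema A `schema_config`.
#' @param path File path.
#' @return `write_schema()` returns `path` invisibly; `read_schema()` returns
#'   a `schema_config`.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(schema_to_list(schema), path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("schema file not found: %s", path))
  schema_from_list(yaml::read_yaml(path))
}
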