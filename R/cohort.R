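#' Label appointment urgency from the scheduling interval
#'
#' An appointment is urgent when it takes place within `threshold_days`
#' days of the date it was scheduled (default two days, the operational
#' cutoff used by echocardiography laboratories for prioritized slots).
#'
#' @param data Cohort tibble with an `interval_days` column (non-negative
#'   integers: days from scheduling to appointment).
#' @param threshold_days Urgency cutoff in days; `urgent = 1` iff
#'   `interval_days <= threshold_days`.
#' @return `data` with the `urgent` column set (overwritten if present).
#' @export
label_urgency <- function(data, threshold_days = 2) {
  if (!"interval_days" %in% names(data)) {
    abort_format("`data` has no `interval_days` column")
  }
  if (any(is.na(data$interval_days)) || any(data$interval_days < 0)) {
    rlang::abort("`interval_days` must be non-negative and complete",
                 class = "echodml_validation_error")
  }
  dplyr::mutate(data, urgent = as.integer(.data$interval_days <= threshold_days))
}

#' Dummy-code a cohort into an analysis design
#'
#' Expands every multi-level administrative variable into a full set of
#' 0/1 indicator columns (`Variable_Level`; all levels kept, no reference
#' level, since effects are later estimated for every level separately) and
#' carries binary flags through unchanged. Constant columns are dropped
#' with a message and recorded. Column metadata remembers each column's
#' source variable, level and group so results can be aggregated back to
#' the administration / comorbidity / referral taxonomy.
#'
#' @param data Cohort tibble; the schema is taken from its `schema`
#'   attribute unless supplied.
#' @param schema Optional `schema_config`.
#' @param outcome Name of the outcome column; by default `"urgent"` when
#'   present, else `"outcome"` (continuous), else none.
#' @return An object of class `urgency_design`: a list with elements
#'   `y` (outcome vector or `NULL`), `x` (tibble of 0/1 columns), `meta`
#'   (tibble: `column`, `source`, `level`, `group`), `id` (row ids), `n`,
#'   and `dropped` (names of constant columns removed).
#' @export
encode_dummies <- function(data, schema = NULL, outcome = NULL) {
  schema <- schema %||% attr(data, "schema")
  if (is.null(schema)) abort_format("no schema attached to the cohort; pass `schema`")
  outcome <- outcome %||%
    (if ("urgent" %in% names(data)) "urgent"
     else if ("outcome" %in% names(data)) "outcome" else NULL)
  vars <- schema_variables(schema)
  missing <- setdiff(vars$variable, names(data))
  if (length(missing)) {
    abort_format(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  cols <- list()
  meta <- list()
  for (nm in names(schema$administrative)) {
    levels <- schema$administrative[[nm]]$levels
    vals <- as.character(data[[nm]])
    bad <- setdiff(unique(vals), levels)
    if (length(bad)) {
      abort_schema(sprintf("variable '%s' has unseen level(s): %s",
                           nm, paste(bad, collapse = ", ")))
    }
    for (lv in levels) {
      cn <- paste(nm, lv, sep = "_")
      cols[[cn]] <- as.integer(vals == lv)
      meta[[cn]] <- tibble::tibble(column = cn, source = nm, level = lv,
                                   group = "administration")
    }
  }
  for (nm in schema_flags(schema)) {
    if (!is_binary01(data[[nm]])) {
      abort_format(sprintf("flag column '%s' contains non-binary values", nm))
    }
    grp <- if (nm %in% names(schema$comorbidity)) "comorbidity" else "referral"
    cols[[nm]] <- as.integer(data[[nm]])
    meta[[nm]] <- tibble::tibble(column = nm, source = nm, level = NA_character_,
                                 group = grp)
  }
  x <- tibble::as_tibble(cols)
  meta <- dplyr::bind_rows(meta)
  constant <- names(x)[vapply(x, function(v) length(unique(v)) < 2, logical(1))]
  if (length(constant)) {
    rlang::inform(sprintf("dropping constant column(s): %s",
                          paste(constant, collapse = ", ")))
    x <- x[, setdiff(names(x), constant), drop = FALSE]
    meta <- meta[!meta$column %in% constant, , drop = FALSE]
  }
  y <- NULL
  if (!is.null(outcome)) {
    if (!outcome %in% names(data)) {
      abort_format(sprintf("outcome column '%s' not found", outcome))
    }
    y <- data[[outcome]]
  }
  structure(
    list(y = y, x = x, meta = meta,
         id = if (".row_id" %in% names(data)) data$.row_id else seq_len(nrow(data)),
         n = nrow(data), dropped = constant, outcome = outcome,
         schema = schema),
    class = "urgency_design"
  )
}

#' @export
print.urgency_design <- function(x, ...) {
  counts <- table(x$meta$group)
  cat(sprintf("<urgency_design> %d rows, %d columns (%s)\n", x$n, nrow(x$meta),
              paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")))
  if (!is.null(x$outcome)) {
    cat(sprintf("  outcome: %s%s\n", x$outcome,
                if (is_binary01(x$y)) sprintf(" (prevalence %.3f)", mean(x$y)) else ""))
  }
  if (length(x$dropped)) cat("  dropped constant columns:", length(x$dropped), "\n")
  invisible(x)
}

#' Reconstruct records from a design matrix
#'
#' Inverse of [encode_dummies()] for the columns that survived encoding:
#' administrative variables are read back from their one-hot blocks, flags
#' are copied through.
#'
#' @param design An `urgency_design`.
#' @return A tibble of reconstructed records.
#' @export
decode_dummies <- function(design) {
  stopifnot(inherits(design, "urgency_design"))
  out <- list()
  meta <- design$meta
  for (src in unique(meta$source)) {
    rows <- meta[meta$source == src, , drop = FALSE]
    if (all(is.na(rows$level))) {
      out[[src]] <- design$x[[rows$column[1]]]
    } else {
      block <- as.matrix(design$x[, rows$column, drop = FALSE])
      out[[src]] <- rows$level[max.col(block)]
    }
  }
  tibble::as_tibble(out)
}

#' Enumerate treatment specifications for a variable group
#'
#' Produces one treatment specification per design column of the chosen
#' group. By default the covariates are all columns of the *other* two
#' groups; sibling indicator columns from the treatment's own source
#' variable are never included (they are deterministic complements of the
#' treatment, which would make the propensity model degenerate).
#'
#' @param design An `urgency_design`.
#' @param group `"administration"`, `"comorbidity"` or `"referral"`.
#' @param include_same_group Also use other same-group variables (excluding
#'   same-source siblings) as covariates.
#' @return A tibble with columns `treatment`, `group`, and `covariates`
#'   (list-column of covariate column names).
#' @export
partition_treatments <- function(design, group, include_same_group = FALSE) {
  stopifnot(inherits(design, "urgency_design"))
  meta <- design$meta
  if (!group %in% meta$group) {
    abort_schema(sprintf("group '%s' has no columns in this design", group))
  }
  trt <- meta[meta$group == group, , drop = FALSE]
  covs <- purrr::map(seq_len(nrow(trt)), function(i) {
    if (include_same_group) {
      keep <- meta$source != trt$source[i]
    } else {
      keep <- meta$group != group
    }
    meta$column[keep]
  })
  tibble::tibble(treatment = trt$column, group = group, covariates = covs)
}
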