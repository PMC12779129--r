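# internal helpers shared across modules

# derive a reproducible child seed from a master seed; stays inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919) %% 2147483647L)
}

clip01 <- function(x, eps = 0) pmin(1 - eps, pmax(eps, x))

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

abort_schema <- function(msg, ...) rlang::abort(msg, class = "echodml_schema_error", ...)
abort_format <- function(msg, ...) rlang::abort(msg, class = "echodml_format_error", ...)
abort_calibration <- function(msg, ...) rlang::abort(msg, class = "echodml_calibration_error", ...)

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  all(x %in% c(0, 1))
}

# draw one categorical level per row from a matrix of per-row logits
sample_levels <- function(logits, levels) {
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  cum <- t(apply(p, 1, cumsum))
  u <- stats::runif(nrow(p))
  idx <- rowSums(u > cum) + 1L
  levels[idx]
}
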