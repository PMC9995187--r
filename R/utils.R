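# Internal helpers shared across modules.

# Validation errors carry class "flutterppi_error" so callers and tests can
# distinguish them from programming errors.
ppi_abort <- function(message, ...) {
  abort(message, class = "flutterppi_error", ...)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ppi_abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    ppi_abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Derive independent sub-seeds from one master seed, so pipeline stages and
# replicate draws are reproducible in isolation. Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Evaluate `expr` under `seed` when supplied, otherwise use the current RNG
# stream (so callers may manage seeding themselves).
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

mechanism_levels <- c("FAFL", "MAFL")
technique_levels <- c("none", "smote", "modified_smote", "smoothed_bootstrap")
classifier_levels <- c("lda", "log", "svm")
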