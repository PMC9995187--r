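# Small in-code fixtures shared across test files.

# Two-record toy cohort with exact, full-precision values.
toy_cohort <- function() {
  cohort(
    record_id = c(rep("f1", 4), rep("m1", 3)),
    mechanism = c(rep("FAFL", 4), rep("MAFL", 3)),
    interval_ms = c(210.125, 255.5, 190.0625, 233.3, 248.1234567, 250, 251.5)
  )
}

# Feature tibble built directly (bypassing interval series) for classifier
# and selection tests: n records per class, `p` feature columns, the first
# informative, the rest noise.
toy_features <- function(n_per_class = 10, p = 3, separation = 3, seed = 42) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    mech <- rep(c("FAFL", "MAFL"), each = n_per_class)
    out <- tibble::tibble(
      record_id = sprintf("r%02d", seq_len(n)),
      mechanism = mech,
      provenance = "original",
      source_record_id = NA_character_
    )
    out$F1 <- rnorm(n) + separation * (mech == "MAFL")
    for (j in seq_len(p - 1)) out[[paste0("F", j + 1)]] <- rnorm(n)
    out
  })
}
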