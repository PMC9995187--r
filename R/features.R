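# Estimators behind the shape features. Skewness is the adjusted
# Fisher-Pearson sample skewness; kurtosis is the Pearson (non-excess)
# moment ratio m4 / m2^2. Both are the feature definitions themselves, so
# they are computed here rather than delegated (tests cross-check them
# against e1071's estimators).
sample_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0 || n < 3L) return(0)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

sample_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

# Mode of continuous interval data: round to the nearest 1 ms, take the most
# frequent value, break ties toward the smallest.
sample_mode <- function(x) {
  r <- round(x)
  tab <- table(r)
  as.numeric(names(tab)[which.max(tab)])
}

feature_names <- c("F1_mean", "F2_median", "F3_mode", "F4_std", "F5_variance",
                   "F6_skewness", "F7_kurtosis", "F8_maximum", "F9_minimum",
                   "F10_sum")

#' Descriptive-statistics features of one interval series
#'
#' The ten features characterising an interval series, grouped as central
#' tendency (mean, median, mode), dispersion (standard deviation, variance;
#' sample n-1 estimators), shape (adjusted Fisher-Pearson skewness, Pearson
#' non-excess kurtosis) and length (maximum, minimum, sum). A constant
#' series has zero variance, so its shape statistics are reported as 0 with
#' the `degenerate` flag set rather than failing — constant synthetic series
#' must remain usable.
#'
#' @param intervals Numeric vector of at least 2 intervals (ms).
#' @param record_id,mechanism Optional metadata carried into the output.
#' @return A one-row tibble: `record_id`, `mechanism`, `F1_mean` ...
#'   `F10_sum`, `degenerate`.
#' @export
#' @examples
#' extract_features(c(220, 231, 228, 225))
extract_features <- function(intervals, record_id = NA_character_,
                             mechanism = NA_character_) {
  if (!is.numeric(intervals) || length(intervals) < 2L) {
    ppi_abort(sprintf("Record '%s': feature extraction needs at least 2 intervals.",
                      record_id))
  }
  v <- var(intervals)
  tibble(
    record_id = record_id,
    mechanism = mechanism,
    F1_mean = mean(intervals),
    F2_median = median(intervals),
    F3_mode = sample_mode(intervals),
    F4_std = sqrt(v),
    F5_variance = v,
    F6_skewness = if (v == 0) 0 else sample_skewness(intervals),
    F7_kurtosis = if (v == 0) 0 else sample_kurtosis(intervals),
    F8_maximum = max(intervals),
    F9_minimum = min(intervals),
    F10_sum = sum(intervals),
    degenerate = v == 0
  )
}

#' Feature matrix for a cohort
#'
#' One row per series in cohort order, the ten descriptive features in fixed
#' column order, plus the metadata needed downstream (mechanism label for
#' supervision, provenance and source record for leakage-safe fold
#' assignment).
#'
#' @param x A cohort tibble.
#' @return A tibble with columns `record_id`, `mechanism`, `provenance`,
#'   `source_record_id`, `F1_mean` ... `F10_sum`, `degenerate`.
#' @export
build_feature_matrix <- function(x) {
  x <- validate_cohort(x)
  if (nrow(x) == 0L) {
    return(dplyr::bind_cols(
      tibble(record_id = character(), mechanism = character(),
             provenance = character(), source_record_id = character()),
      as_tibble(stats::setNames(rep(list(numeric()), length(feature_names)),
                                feature_names)),
      tibble(degenerate = logical())
    ))
  }
  meta <- dplyr::distinct(x, .data$record_id, .data$mechanism,
                          .data$provenance, .data$source_record_id)
  feats <- x %>%
    dplyr::group_by(.data$record_id) %>%
    dplyr::group_map(~ extract_features(.x$interval_ms, record_id = .y$record_id,
                                        mechanism = .x$mechanism[1]))
  feats <- dplyr::bind_rows(feats)
  # group_map sorts by key; restore cohort order
  feats <- feats[match(meta$record_id, feats$record_id), ]
  dplyr::bind_cols(meta[, c("record_id", "mechanism", "provenance", "source_record_id")],
                   feats[, c(feature_names, "degenerate")])
}
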