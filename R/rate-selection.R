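#' Maximum specificity per feature-combination length
#'
#' For each combination length `L`, evaluates every length-`L` feature
#' subset by cross-validation and records the maximum specificity achieved.
#' Specificity (FAFL true-negative rate) is the metric the augmentation is
#' meant to rescue under imbalance, so its best-case profile over subset
#' lengths characterises a rate/technique setting.
#'
#' @param features A feature matrix from [build_feature_matrix()] (typically
#'   of an augmented cohort).
#' @param classifier `"lda"`, `"log"` or `"svm"`.
#' @param feature_cols Feature columns to search over.
#' @param k,seed,grouped Cross-validation settings (folds fixed once and
#'   reused across subsets).
#' @return A tibble with `length`, `specificity` (percent) and
#'   `best_subset`.
#' @export
specificity_by_length <- function(features, classifier = c("lda", "log", "svm"),
                                  feature_cols = feature_names, k = 5, seed = 1,
                                  grouped = TRUE) {
  classifier <- match.arg(classifier)
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  y <- features$mechanism
  folds <- assign_folds(features, k = k, seed = seed, grouped = grouped)
  subsets <- enumerate_subsets(length(feature_cols))
  purrr::imap_dfr(subsets, function(group, nm) {
    spec <- vapply(group, function(cols) {
      tryCatch({
        per_fold <- cv_confusions(X[, cols, drop = FALSE], y, folds, classifier)
        m <- mean(per_fold$specificity, na.rm = TRUE)
        if (is.nan(m)) 0 else m
      }, error = function(e) 0)
    }, numeric(1))
    best <- which.max(spec)
    tibble(length = length(group[[1]]),
           specificity = spec[best],
           best_subset = paste(feature_cols[group[[best]]], collapse = "+"))
  })
}

#' Specificity curve of an augmentation setting
#'
#' Augments a cohort at the given technique and rate, extracts features, and
#' computes the [specificity_by_length()] profile.
#'
#' @param x A cohort tibble of original series.
#' @param technique Augmentation technique; ignored at `rate_percent = 0`.
#' @param rate_percent Augmentation rate (multiple of 100; 0 = none).
#' @param classifier,feature_cols,k,grouped As in [specificity_by_length()].
#' @param seed Seed shared by the augmentation draws and the fold
#'   assignment.
#' @return A tibble with `rate_percent`, `length`, `specificity`,
#'   `best_subset`.
#' @export
specificity_curve <- function(x, technique = "modified_smote", rate_percent = 400,
                              classifier = c("lda", "log", "svm"),
                              feature_cols = feature_names, k = 5, seed = 1,
                              grouped = TRUE) {
  classifier <- match.arg(classifier)
  aug <- if (rate_percent == 0) validate_cohort(x) else
    augment_cohort(x, augmentation_config(technique, rate_percent, seed = seed))
  feats <- build_feature_matrix(aug)
  curve <- specificity_by_length(feats, classifier, feature_cols, k = k,
                                 seed = seed, grouped = grouped)
  dplyr::bind_cols(tibble(rate_percent = rate_percent), curve)
}

#' Select the best augmentation rate
#'
#' Given per-rate specificity curves over combination lengths, computes the
#' pointwise average curve across rates and the Euclidean distance of each
#' rate's curve to it; the best rate minimises that distance, with ties
#' resolved to the smallest rate (preferring the minimum synthetic ratio).
#'
#' @param curves A tibble with columns `rate_percent`, `length` and
#'   `specificity` covering at least two rates, all with curves over the
#'   same lengths.
#' @return A `ppi_rate_selection` object: `curves`, `average_curve`,
#'   `distances` (per-rate Euclidean distance to the average) and
#'   `best_rate_percent`. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' curves <- tidyr::expand_grid(rate_percent = c(100, 200, 300), length = 1:3)
#' curves$specificity <- c(10, 20, 30, 20, 30, 40, 30, 40, 50)
#' select_best_rate(curves)$best_rate_percent
select_best_rate <- function(curves) {
  needed <- c("rate_percent", "length", "specificity")
  if (!all(needed %in% names(curves))) {
    ppi_abort("`curves` needs columns rate_percent, length, specificity.")
  }
  rates <- sort(unique(curves$rate_percent))
  if (length(rates) < 2L) ppi_abort("Need curves for at least 2 rates.")
  wide <- curves %>%
    dplyr::select(dplyr::all_of(needed)) %>%
    dplyr::arrange(.data$rate_percent, .data$length) %>%
    tidyr::pivot_wider(names_from = "rate_percent", values_from = "specificity")
  if (anyNA(wide)) {
    ppi_abort("All rates must provide a specificity value at every combination length.")
  }
  mat <- as.matrix(wide[, -1, drop = FALSE])
  avg <- rowMeans(mat)
  dist <- sqrt(colSums((mat - avg)^2))
  best <- rates[which.min(dist)] # which.min takes the first = smallest rate on ties
  structure(list(
    curves = curves,
    average_curve = tibble(length = wide$length, specificity = avg),
    distances = tibble(rate_percent = rates, distance = unname(dist)),
    best_rate_percent = best
  ), class = "ppi_rate_selection")
}

#' @export
print.ppi_rate_selection <- function(x, ...) {
  cat(sprintf("Best augmentation rate: %d%% (minimum distance to the average specificity curve)\n",
              x$best_rate_percent))
  print(x$distances)
  invisible(x)
}
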