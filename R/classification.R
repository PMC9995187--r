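# Linear classifiers with fixed, logged settings: LDA with pooled covariance
# (MASS::lda), logistic regression without regularization (glm.fit,
# binomial), linear-kernel SVM with unit cost (e1071::svm). Features are
# standardized per training fold before fitting.

classifier_settings <- list(
  lda = "MASS::lda, pooled covariance, default priors",
  log = "stats::glm.fit, binomial logit, no regularization, 0.5 threshold",
  svm = "e1071::svm, linear kernel, cost 1"
)

fit_predict <- function(train_x, train_y, test_x, classifier) {
  classifier <- match.arg(classifier, classifier_levels)
  lv <- mechanism_levels
  if (classifier == "lda") {
    fit <- MASS::lda(train_x, grouping = train_y)
    as.character(predict(fit, test_x)$class)
  } else if (classifier == "log") {
    y01 <- as.integer(train_y == "MAFL")
    # perfect separation warnings are expected on small separable folds
    fit <- suppressWarnings(glm.fit(cbind(1, train_x), y01, family = binomial()))
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    p <- plogis(drop(cbind(1, test_x) %*% beta))
    ifelse(p >= 0.5, "MAFL", "FAFL")
  } else {
    fit <- e1071::svm(train_x, factor(train_y, levels = lv),
                      kernel = "linear", cost = 1, scale = FALSE)
    as.character(predict(fit, test_x))
  }
}

standardize_fold <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sg <- apply(train_x, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(train = sweep(sweep(train_x, 2, mu), 2, sg, "/"),
       test = sweep(sweep(test_x, 2, mu), 2, sg, "/"))
}

#' Leakage-safe stratified fold assignment
#'
#' Original records are assigned to folds by stratified random allocation
#' within each mechanism class; every synthetic series is then placed in the
#' same fold as the original record it was generated from, so a record and
#' its synthetic offspring never straddle the train/test boundary.
#'
#' @param features A feature matrix from [build_feature_matrix()] (needs
#'   `record_id`, `mechanism`, `provenance`, `source_record_id`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the allocation.
#' @param grouped Set `FALSE` to ignore provenance and stratify all series
#'   independently (sensitivity analysis only; permits leakage).
#' @return Integer vector of fold ids (1..k), one per feature-matrix row.
#' @export
assign_folds <- function(features, k = 5, seed = 1, grouped = TRUE) {
  needed <- c("record_id", "mechanism", "provenance", "source_record_id")
  if (!all(needed %in% names(features))) {
    ppi_abort("`features` needs record_id, mechanism, provenance and source_record_id columns.")
  }
  withr::with_seed(seed, {
    if (grouped) {
      anchor <- ifelse(features$provenance == "synthetic",
                       features$source_record_id, features$record_id)
      if (any(is.na(anchor))) {
        ppi_abort("Synthetic series without a source_record_id cannot be folded safely.")
      }
      originals <- features[features$provenance == "original", ]
      fold_of <- unlist(lapply(split(originals$record_id, originals$mechanism), function(ids) {
        ids <- sample(ids)
        stats::setNames(rep_len(seq_len(k), length(ids)), ids)
      }))
      names(fold_of) <- sub("^(FAFL|MAFL)\\.", "", names(fold_of))
      unknown <- setdiff(unique(anchor), names(fold_of))
      if (length(unknown)) {
        ppi_abort(sprintf("Synthetic series reference unknown source record '%s'.", unknown[1]))
      }
      folds <- unname(fold_of[anchor])
    } else {
      folds <- integer(nrow(features))
      for (i in split(seq_len(nrow(features)), features$mechanism)) {
        folds[sample(i)] <- rep_len(seq_len(k), length(i))
      }
    }
    check_fold_classes(features$mechanism, folds, k)
    folds
  })
}

check_fold_classes <- function(mechanism, folds, k) {
  for (f in seq_len(k)) {
    train <- mechanism[folds != f]
    if (length(unique(train)) < 2L) {
      ppi_abort(sprintf(
        "Training fold %d contains a single class; use fewer folds or a larger cohort.", f))
    }
  }
  invisible(folds)
}

confusion_counts <- function(truth, predicted) {
  c(TP = sum(truth == "MAFL" & predicted == "MAFL"),
    FP = sum(truth == "FAFL" & predicted == "MAFL"),
    TN = sum(truth == "FAFL" & predicted == "FAFL"),
    FN = sum(truth == "MAFL" & predicted == "FAFL"))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity and specificity in percent, with the macroreentrant
#' class (MAFL) as the positive class throughout: sensitivity is the MAFL
#' true-positive rate, specificity the FAFL true-negative rate.
#'
#' @param TP,FP,TN,FN Confusion counts (MAFL positive).
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity` in
#'   percent; a metric with an empty denominator is `NA`.
#' @export
#' @examples
#' classification_metrics(TP = 9, FP = 1, TN = 1, FN = 1)
classification_metrics <- function(TP, FP, TN, FN) {
  div <- function(num, den) if (den == 0) NA_real_ else unname(100 * num / den)
  c(accuracy = div(TP + TN, TP + TN + FP + FN),
    sensitivity = div(TP, TP + FN),
    specificity = div(TN, TN + FP))
}

cv_confusions <- function(X, y, folds, classifier) {
  k <- max(folds)
  purrr::map_dfr(seq_len(k), function(f) {
    te <- folds == f
    if (!any(te)) return(NULL)
    std <- standardize_fold(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    pred <- fit_predict(std$train, y[!te], std$test, classifier)
    cc <- confusion_counts(y[te], pred)
    m <- classification_metrics(cc["TP"], cc["FP"], cc["TN"], cc["FN"])
    tibble(fold = f, TP = cc[["TP"]], FP = cc[["FP"]], TN = cc[["TN"]],
           FN = cc[["FN"]], accuracy = m[["accuracy"]],
           sensitivity = m[["sensitivity"]], specificity = m[["specificity"]])
  })
}

#' Cross-validated evaluation of a linear classifier
#'
#' Stratified, leakage-safe k-fold cross-validation (see [assign_folds()]):
#' features are standardized per training fold, the classifier is fitted and
#' the held-out fold predicted. Metrics use MAFL as the positive class and
#' are reported per fold, as fold means, and from the pooled confusion
#' counts.
#'
#' @param features A feature matrix from [build_feature_matrix()].
#' @param classifier `"lda"`, `"log"` or `"svm"`.
#' @param feature_cols Which feature columns to use (default all ten).
#' @param k,seed Cross-validation folds and seed.
#' @param grouped Passed to [assign_folds()].
#' @return A `ppi_performance` object with `per_fold` (confusion counts and
#'   metrics per fold), `summary` (fold means and SDs plus pooled metrics),
#'   and the settings used. Has [tidy()] and [glance()] methods.
#' @export
evaluate_classifier <- function(features, classifier = c("lda", "log", "svm"),
                                feature_cols = feature_names, k = 5, seed = 1,
                                grouped = TRUE) {
  classifier <- match.arg(classifier)
  missing_f <- setdiff(feature_cols, names(features))
  if (length(missing_f)) {
    ppi_abort(sprintf("Feature column '%s' not found.", missing_f[1]))
  }
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  y <- features$mechanism
  folds <- assign_folds(features, k = k, seed = seed, grouped = grouped)
  per_fold <- cv_confusions(X, y, folds, classifier)
  pooled <- classification_metrics(sum(per_fold$TP), sum(per_fold$FP),
                                   sum(per_fold$TN), sum(per_fold$FN))
  summary <- tibble(
    classifier = classifier,
    accuracy = mean(per_fold$accuracy, na.rm = TRUE),
    accuracy_sd = sd(per_fold$accuracy, na.rm = TRUE),
    sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
    sensitivity_sd = sd(per_fold$sensitivity, na.rm = TRUE),
    specificity = mean(per_fold$specificity, na.rm = TRUE),
    specificity_sd = sd(per_fold$specificity, na.rm = TRUE),
    accuracy_pooled = pooled[["accuracy"]],
    sensitivity_pooled = pooled[["sensitivity"]],
    specificity_pooled = pooled[["specificity"]]
  )
  structure(list(per_fold = per_fold, summary = summary,
                 classifier = classifier, feature_cols = feature_cols,
                 k = k, seed = seed, grouped = grouped,
                 settings = classifier_settings[[classifier]]),
            class = "ppi_performance")
}

#' @export
print.ppi_performance <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated %s (%s)\n", x$k, toupper(x$classifier),
              x$settings))
  print(x$summary)
  invisible(x)
}
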