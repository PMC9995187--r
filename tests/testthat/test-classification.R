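test_that("metrics follow the confusion-matrix identities with MAFL positive", {
  m <- classification_metrics(TP = 9, FP = 1, TN = 1, FN = 1)
  expect_equal(m[["sensitivity"]], 90)
  expect_equal(m[["specificity"]], 50)
  expect_equal(m[["accuracy"]], 100 * 10 / 12)

  # the imbalance pathology: a majority-class predictor on an 8:1 cohort
  m <- classification_metrics(TP = 8, FP = 1, TN = 0, FN = 0)
  expect_equal(m[["sensitivity"]], 100)
  expect_equal(m[["specificity"]], 0)
  expect_equal(m[["accuracy"]], 100 * 8 / 9, tolerance = 1e-12)

  # empty denominator yields NA, not a crash
  expect_true(is.na(classification_metrics(0, 0, 0, 0)[["accuracy"]]))
})

test_that("all three linear classifiers solve a cleanly separable problem", {
  feats <- toy_features(n_per_class = 8, p = 2, separation = 10)
  for (cl in c("lda", "log", "svm")) {
    g <- glance(evaluate_classifier(feats, cl, feature_cols = c("F1", "F2"),
                                    k = 4, seed = 2))
    expect_equal(g$accuracy, 100)
    expect_equal(g$sensitivity, 100)
    expect_equal(g$specificity, 100)
  }
})

test_that("per-fold reports respect the metric identities", {
  co <- generate_cohort(cohort_spec(n_fafl = 4, n_mafl = 12), seed = 3)
  perf <- evaluate_classifier(build_feature_matrix(co), "log", k = 4, seed = 5)
  pf <- tidy(perf)
  for (i in seq_len(nrow(pf))) {
    m <- classification_metrics(pf$TP[i], pf$FP[i], pf$TN[i], pf$FN[i])
    expect_equal(pf$accuracy[i], m[["accuracy"]])
    expect_equal(pf$sensitivity[i], m[["sensitivity"]])
    expect_equal(pf$specificity[i], m[["specificity"]])
  }
  g <- glance(perf)
  expect_true(all(dplyr::between(
    c(g$accuracy, g$sensitivity, g$specificity), 0, 100)))
})

test_that("synthetic series are folded with their source record, never apart", {
  co <- generate_cohort(cohort_spec(n_fafl = 4, n_mafl = 8), seed = 1)
  aug <- augment_cohort(co, augmentation_config("smote", 300, seed = 9))
  feats <- build_feature_matrix(aug)
  folds <- assign_folds(feats, k = 4, seed = 2)
  fold_of <- stats::setNames(folds, feats$record_id)
  syn <- feats[feats$provenance == "synthetic", ]
  # exhaustive guard: every synthetic shares its source's fold
  expect_true(all(fold_of[syn$record_id] == fold_of[syn$source_record_id]))

  # without synthetics, plain stratified folds cover all records
  f0 <- assign_folds(build_feature_matrix(co), k = 4, seed = 2)
  expect_equal(sort(unique(f0)), 1:4)

  bad <- syn[1, ]
  bad$source_record_id <- "ghost"
  expect_error(assign_folds(dplyr::bind_rows(feats, bad), k = 4, seed = 2),
               "ghost", class = "flutterppi_error")

  # a training fold missing a class is refused with advice
  tiny <- generate_cohort(cohort_spec(n_fafl = 1, n_mafl = 6), seed = 1)
  expect_error(assign_folds(build_feature_matrix(tiny), k = 3, seed = 1),
               "fewer folds", class = "flutterppi_error")
})

test_that("specificity curves report the best subset per combination length", {
  feats <- toy_features(n_per_class = 6, p = 2, separation = 6)
  curve <- specificity_by_length(feats, "lda", feature_cols = c("F1", "F2"),
                                 k = 3, seed = 4)
  expect_equal(curve$length, 1:2)
  expect_true(all(dplyr::between(curve$specificity, 0, 100)))

  # a single-feature search reduces to that feature's cross-validated specificity
  single <- specificity_by_length(feats, "lda", feature_cols = "F1", k = 3, seed = 4)
  direct <- glance(evaluate_classifier(feats, "lda", feature_cols = "F1",
                                       k = 3, seed = 4))
  expect_equal(single$specificity, direct$specificity)
})

test_that("rate selection minimises distance to the average curve, ties to the smallest rate", {
  flat <- tidyr::expand_grid(rate_percent = c(100, 200, 400), length = 1:4)
  flat$specificity <- rep(c(20, 35, 40, 42), 3)
  sel <- select_best_rate(flat)
  expect_equal(sel$distances$distance, rep(0, 3))
  expect_equal(sel$best_rate_percent, 100) # tie -> minimum synthetic ratio

  # a curve equal to the average of the others is itself the average curve
  a <- c(10, 20, 30); b <- c(30, 40, 50)
  curves <- tibble::tibble(
    rate_percent = rep(c(100, 200, 300), each = 3),
    length = rep(1:3, 3),
    specificity = c(a, (a + b) / 2, b)
  )
  expect_equal(select_best_rate(curves)$best_rate_percent, 200)

  # constructed 3-rate example against hand-computed Euclidean distances
  set <- tibble::tibble(
    rate_percent = rep(c(100, 200, 300), each = 2),
    length = rep(1:2, 3),
    specificity = c(10, 50, 30, 20, 80, 35)
  )
  mat <- matrix(set$specificity, nrow = 2)
  avg <- rowMeans(mat)
  d <- sqrt(colSums((mat - avg)^2))
  sel <- select_best_rate(set)
  expect_equal(sel$distances$distance, unname(d))
  expect_equal(sel$best_rate_percent, c(100, 200, 300)[which.min(d)])

  ragged <- flat[-1, ]
  expect_error(select_best_rate(ragged), class = "flutterppi_error")
})
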