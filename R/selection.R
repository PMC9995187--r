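#' Filter feature relevance: Wilcoxon rank-sum p-values
#'
#' Two-sided rank-sum test of each feature between the two mechanism
#' classes, testing for a significant difference in medians. The exact
#' distribution is enumerated when both groups have at most 10 samples (and
#' no ties); the normal approximation is used otherwise.
#'
#' @param features A feature matrix from [build_feature_matrix()].
#' @param feature_cols Feature columns to test (default all ten).
#' @return A tibble with `feature`, `p_value` and `significant`
#'   (`p_value < 0.05`).
#' @export
filter_pvalues <- function(features, feature_cols = feature_names) {
  y <- features$mechanism
  if (length(unique(y)) < 2L) {
    ppi_abort("Both mechanism classes must be present for the rank-sum filter.")
  }
  g1 <- y == mechanism_levels[1]
  exact <- sum(g1) <= 10 && sum(!g1) <= 10
  p <- vapply(feature_cols, function(f) {
    v <- features[[f]]
    # ties force wilcox.test onto the approximate path with a warning
    pv <- suppressWarnings(
      wilcox.test(v[g1], v[!g1], exact = exact, correct = !exact)$p.value
    )
    # a feature constant everywhere carries no rank information at all
    if (is.nan(pv)) 1 else pv
  }, numeric(1))
  tibble(feature = feature_cols, p_value = unname(p), significant = unname(p) < 0.05)
}

#' Enumerate all non-empty feature subsets
#'
#' All `2^p - 1` combinations of `p` features, grouped by combination
#' length; within each length subsets are in lexicographic order.
#'
#' @param p Number of features (1..20; the exhaustive wrapper is intractable
#'   beyond that).
#' @return A list with one element per length `L`, each a list of
#'   `choose(p, L)` integer vectors.
#' @export
#' @examples
#' length(unlist(enumerate_subsets(10), recursive = FALSE)) # 1023
enumerate_subsets <- function(p) {
  stopifnot_scalar_number(p, "p")
  if (p < 1 || p > 20 || p %% 1 != 0) {
    ppi_abort("`p` must be an integer in 1..20.")
  }
  stats::setNames(lapply(seq_len(p), function(L) {
    m <- combn(p, L)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  }), paste0("length_", seq_len(p)))
}

#' Wrapper feature relevance: exhaustive subset scoring
#'
#' Every non-empty feature subset is evaluated by cross-validated accuracy.
#' For each combination length, the subset with the maximum accuracy is
#' found and each of its member features is credited 1; a feature's score is
#' its total credit divided by the number of features, so scores lie on the
#' grid `{0, 1/p, ..., 1}` and features with scores near 1 recur in the best
#' combination at almost every length. Ties for the best subset at a length
#' are broken toward the lexicographically first subset (and counted).
#'
#' @param features A feature matrix from [build_feature_matrix()].
#' @param classifier `"lda"`, `"log"` or `"svm"`.
#' @param feature_cols Feature columns to score.
#' @param k,seed Cross-validation folds and seed; the same fold assignment
#'   is reused for every subset so accuracies are comparable.
#' @param grouped Passed to [assign_folds()].
#' @return A `ppi_scores` object: `scores` (per-feature score and credit
#'   count), `log` (accuracy of every subset at every length, with the best
#'   flagged), `n_ties` and the settings. Has a [tidy()] method.
#' @export
wrapper_scores <- function(features, classifier = c("lda", "log", "svm"),
                           feature_cols = feature_names, k = 5, seed = 1,
                           grouped = TRUE) {
  classifier <- match.arg(classifier)
  p <- length(feature_cols)
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  y <- features$mechanism
  folds <- assign_folds(features, k = k, seed = seed, grouped = grouped)

  subset_accuracy <- function(cols) {
    tryCatch({
      per_fold <- cv_confusions(X[, cols, drop = FALSE], y, folds, classifier)
      mean(per_fold$accuracy, na.rm = TRUE)
    }, error = function(e) {
      warn(sprintf("Classifier failed on subset {%s}; scored as accuracy 0 (%s).",
                   paste(feature_cols[cols], collapse = ", "), conditionMessage(e)))
      0
    })
  }

  subsets <- enumerate_subsets(p)
  credit <- stats::setNames(integer(p), feature_cols)
  n_ties <- 0L
  eval_log <- purrr::imap_dfr(subsets, function(group, group_name) {
    acc <- vapply(group, subset_accuracy, numeric(1))
    best <- which.max(acc) # first maximum = lexicographically first subset
    n_ties <<- n_ties + max(0L, sum(acc == acc[best]) - 1L)
    credit[feature_cols[group[[best]]]] <<- credit[feature_cols[group[[best]]]] + 1L
    tibble(length = length(group[[1]]),
           subset = vapply(group, function(s) paste(feature_cols[s], collapse = "+"),
                           character(1)),
           accuracy = acc,
           best = seq_along(group) == best)
  })
  scores <- tibble(feature = feature_cols, credit = unname(credit),
                   score = unname(credit) / p, classifier = classifier)
  structure(list(scores = scores, log = eval_log, n_ties = n_ties,
                 classifier = classifier, k = k, seed = seed),
            class = "ppi_scores")
}

#' @export
print.ppi_scores <- function(x, ...) {
  cat(sprintf("Wrapper feature scores (%s, %d-fold CV, %d tie(s) at best subsets)\n",
              toupper(x$classifier), x$k, x$n_ties))
  print(x$scores)
  invisible(x)
}

#' Combined filter and wrapper score table
#'
#' Runs the rank-sum filter once and the exhaustive wrapper for each
#' requested classifier, and combines them into one relevance table. A
#' feature is called relevant when its wrapper score reaches
#' `score_threshold` (default 0.8) for a majority of the classifiers;
#' relevant features are ordered by mean wrapper score, then by filter
#' p-value.
#'
#' @param features A feature matrix from [build_feature_matrix()].
#' @param classifiers Classifiers to run the wrapper with.
#' @param feature_cols Feature columns to assess.
#' @param k,seed,grouped Cross-validation settings shared by all wrappers.
#' @param score_threshold Wrapper relevance threshold.
#' @return A `ppi_score_table`: `table` (per feature: filter p, one wrapper
#'   score column per classifier, relevance flag), plus the underlying
#'   [wrapper_scores()] objects.
#' @export
feature_score_table <- function(features, classifiers = classifier_levels,
                                feature_cols = feature_names, k = 5, seed = 1,
                                grouped = TRUE, score_threshold = 0.8) {
  filt <- filter_pvalues(features, feature_cols)
  wraps <- purrr::map(stats::setNames(classifiers, classifiers), function(cl) {
    wrapper_scores(features, cl, feature_cols, k = k, seed = seed, grouped = grouped)
  })
  tab <- filt[, c("feature", "p_value")]
  for (cl in classifiers) {
    tab[[paste0("score_", cl)]] <- wraps[[cl]]$scores$score
  }
  score_mat <- as.matrix(tab[, paste0("score_", classifiers), drop = FALSE])
  tab$mean_score <- rowMeans(score_mat)
  tab$relevant <- rowSums(score_mat >= score_threshold) > length(classifiers) / 2
  tab <- dplyr::arrange(tab, dplyr::desc(.data$relevant),
                        dplyr::desc(.data$mean_score), .data$p_value)
  structure(list(table = tab, wrappers = wraps,
                 score_threshold = score_threshold, k = k, seed = seed),
            class = "ppi_score_table")
}

#' @export
print.ppi_score_table <- function(x, ...) {
  cat(sprintf("Feature relevance (filter rank-sum p + wrapper scores; threshold %.2f)\n",
              x$score_threshold))
  print(x$table)
  invisible(x)
}
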