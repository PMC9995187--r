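#' Binned empirical CDF
#'
#' Cumulative fraction of intervals falling at or below each bin edge, with
#' edges on a fixed grid of `bin_width` multiples spanning the data. Binning
#' onto a common grid lets CDFs of different datasets be compared pointwise.
#'
#' @param data Non-empty numeric vector (ms).
#' @param bin_width Bin size in ms; default 5 ms.
#' @param range Optional numeric length-2 vector forcing the grid span (used
#'   to place two datasets on a shared grid).
#' @return A tibble with `edge` (upper bin edge) and `cum_frac`,
#'   non-decreasing with final value 1.
#' @export
#' @examples
#' empirical_cdf(c(95, 105), bin_width = 5)
empirical_cdf <- function(data, bin_width = 5, range = NULL) {
  if (length(data) == 0L || !is.numeric(data)) ppi_abort("`data` must be non-empty numeric.")
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  span <- if (is.null(range)) base::range(data) else range
  lo <- floor(span[1] / bin_width) * bin_width
  hi <- ceiling(span[2] / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)[-1]
  tibble(edge = edges,
         cum_frac = vapply(edges, function(e) mean(data <= e), numeric(1)))
}

#' Maximum pointwise difference between two binned CDFs
#'
#' Both datasets are binned on a shared grid; returns
#' `max |F_original - F_augmented|` over the bin edges.
#'
#' @param original,augmented Non-empty numeric vectors (ms).
#' @param bin_width Bin size in ms.
#' @return A single number in `[0, 1]`.
#' @export
cdf_max_abs_diff <- function(original, augmented, bin_width = 5) {
  span <- base::range(c(original, augmented))
  f0 <- empirical_cdf(original, bin_width, range = span)
  f1 <- empirical_cdf(augmented, bin_width, range = span)
  max(abs(f0$cum_frac - f1$cum_frac))
}

#' Quartile differences between original and augmented data
#'
#' Absolute differences of the 25%, 50% and 75% sample quantiles (linear
#' interpolation between order statistics, the [stats::quantile()] type-7
#' default).
#'
#' @param original,augmented Non-empty numeric vectors (ms).
#' @return Named numeric vector `c(q25, q50, q75)` in ms.
#' @export
quartile_differences <- function(original, augmented) {
  if (length(original) == 0L || length(augmented) == 0L) {
    ppi_abort("Both inputs must be non-empty.")
  }
  probs <- c(0.25, 0.5, 0.75)
  d <- abs(quantile(augmented, probs, names = FALSE) -
             quantile(original, probs, names = FALSE))
  stats::setNames(d, c("q25", "q50", "q75"))
}

#' Kolmogorov-Smirnov similarity between original and augmented replicates
#'
#' Two-sample KS test (asymptotic p-value) of each augmented replicate
#' against the original data; the p-value is read as a similarity measure
#' (larger means the augmented distribution is harder to tell apart from the
#' original), summarised as mean and SD across replicates.
#'
#' @param original Non-empty numeric vector (ms).
#' @param augmented_replicates List of numeric vectors, one per replicate.
#' @return A list with `mean_p`, `sd_p`, `p_values`, `n_used` and
#'   `n_skipped` (replicates with fewer than 2 points are skipped with a
#'   warning).
#' @export
ks_similarity <- function(original, augmented_replicates) {
  if (!is.list(augmented_replicates) || length(augmented_replicates) == 0L) {
    ppi_abort("`augmented_replicates` must be a non-empty list.")
  }
  usable <- vapply(augmented_replicates, function(r) length(r) >= 2L, logical(1))
  if (any(!usable)) {
    warn(sprintf("%d replicate(s) with fewer than 2 points skipped.", sum(!usable)))
  }
  p <- vapply(augmented_replicates[usable], function(r) {
    # ties are expected (bootstrap replicates reuse original points); the
    # asymptotic p-value remains the intended similarity measure
    suppressWarnings(ks.test(original, r, exact = FALSE)$p.value)
  }, numeric(1))
  list(mean_p = mean(p), sd_p = if (length(p) > 1) sd(p) else NA_real_,
       p_values = p, n_used = sum(usable), n_skipped = sum(!usable))
}

#' Percent differences in descriptive moments
#'
#' Signed percent differences `100 * (augmented - original) / original` for
#' the sample mean, sample variance and sample skewness. When an original
#' moment is (numerically) zero the percent difference is undefined; the
#' absolute difference is reported instead and flagged.
#'
#' @param original,augmented Non-empty numeric vectors (ms).
#' @return A tibble with `moment`, `original`, `augmented`, `percent_diff`,
#'   `absolute_diff` and `absolute_fallback` (TRUE where the percent is a
#'   flagged absolute difference).
#' @export
moment_percent_differences <- function(original, augmented) {
  if (length(original) < 2L || length(augmented) < 2L) {
    ppi_abort("Both inputs need at least 2 points.")
  }
  moments <- function(x) c(mean = mean(x), variance = var(x),
                           skewness = sample_skewness(x))
  m0 <- moments(original)
  m1 <- moments(augmented)
  zero <- unname(abs(m0) < 1e-12)
  tibble(
    moment = names(m0),
    original = unname(m0),
    augmented = unname(m1),
    percent_diff = ifelse(zero, unname(m1 - m0), 100 * unname(m1 - m0) / unname(m0)),
    absolute_diff = unname(m1 - m0),
    absolute_fallback = unname(zero)
  )
}

#' Rank augmentation techniques per validation criterion
#'
#' Assigns ranks 1 (best) to 3 per criterion: for criteria where smaller is
#' better (CDF max difference, quartile differences, absolute moment
#' differences) the smallest value gets rank 1; for the KS similarity the
#' largest p gets rank 1. Ties share the better rank.
#'
#' @param criteria A tibble with columns `criterion`, `technique`, `value`
#'   and `direction` (`"lower"` or `"higher"` = which value is better), with
#'   all three techniques present for every criterion.
#' @return The input with a `rank` column appended.
#' @export
rank_techniques <- function(criteria) {
  needed <- c("criterion", "technique", "value", "direction")
  if (!all(needed %in% names(criteria))) {
    ppi_abort("`criteria` needs columns criterion, technique, value, direction.")
  }
  incomplete <- criteria %>%
    dplyr::group_by(.data$criterion) %>%
    dplyr::summarise(n = dplyr::n_distinct(.data$technique),
                     na = any(is.na(.data$value)), .groups = "drop") %>%
    dplyr::filter(.data$n != 3L | .data$na)
  if (nrow(incomplete)) {
    ppi_abort(sprintf("Criterion '%s' is missing a technique or a value.",
                      incomplete$criterion[1]))
  }
  criteria %>%
    dplyr::group_by(.data$criterion) %>%
    dplyr::mutate(rank = if (.data$direction[1] == "higher") {
      base::rank(-.data$value, ties.method = "min")
    } else {
      base::rank(.data$value, ties.method = "min")
    }) %>%
    dplyr::ungroup()
}

#' Run the four-test augmentation validation battery
#'
#' For each technique, `n_replicates` augmented datasets are generated at the
#' given rate; each replicate's augmented minority dataset (original plus
#' synthetic intervals, pooled) is compared to the original minority
#' intervals by (1) maximum binned-CDF difference, (2) quartile differences,
#' (3) two-sample KS similarity and (4) percent differences of mean,
#' variance and skewness. Replicate-averaged statistics are then ranked
#' across techniques.
#'
#' @param x A cohort tibble (original series; any synthetic rows are ignored
#'   for the original reference).
#' @param rate_percent Augmentation rate (default the study's best rate,
#'   400%).
#' @param techniques Character vector of techniques to compare.
#' @param n_replicates Augmented datasets per technique (default 100).
#' @param bin_width CDF bin size (ms).
#' @param seed Master seed; replicate seeds are derived from it.
#' @return A `ppi_validation` object: list with `summary` (per-technique
#'   replicate-averaged statistics), `ranks` (see [rank_techniques()]),
#'   `cdf` (average binned CDFs), and the settings. Has [tidy()], [glance()]
#'   and [ggplot2::autoplot()] methods.
#' @export
validate_augmentation <- function(x, rate_percent = 400,
                                  techniques = c("smote", "modified_smote", "smoothed_bootstrap"),
                                  n_replicates = 100, bin_width = 5, seed = 1) {
  x <- validate_cohort(x)
  minority <- minority_class(x)
  original <- x %>%
    dplyr::filter(.data$provenance == "original", .data$mechanism == minority) %>%
    dplyr::pull(.data$interval_ms)
  if (length(original) < 2L) ppi_abort("Need at least 2 original minority intervals.")
  seeds <- matrix(derive_seeds(seed, n_replicates * length(techniques)),
                  nrow = n_replicates)
  span <- base::range(original) + c(-4, 4) * sd(original)

  per_tech <- purrr::imap(stats::setNames(techniques, techniques), function(tech, nm) {
    i <- match(tech, techniques)
    reps <- purrr::map(seq_len(n_replicates), function(r) {
      cfg <- augmentation_config(tech, rate_percent, seed = seeds[r, i])
      aug <- augment_cohort(x, cfg)
      aug %>%
        dplyr::filter(.data$mechanism == minority) %>%
        dplyr::pull(.data$interval_ms)
    })
    ks <- ks_similarity(original, reps)
    qd <- purrr::map(reps, ~ quartile_differences(original, .x))
    cdfd <- vapply(reps, function(r) cdf_max_abs_diff(original, r, bin_width), numeric(1))
    mom <- purrr::map_dfr(reps, ~ moment_percent_differences(original, .x)) %>%
      dplyr::group_by(.data$moment) %>%
      dplyr::summarise(percent_diff = mean(.data$percent_diff),
                       absolute_fallback = any(.data$absolute_fallback),
                       .groups = "drop")
    cdf_grid <- purrr::map(reps, ~ empirical_cdf(.x, bin_width, range = span))
    avg_cdf <- tibble(edge = cdf_grid[[1]]$edge,
                      cum_frac = Reduce(`+`, purrr::map(cdf_grid, "cum_frac")) / length(cdf_grid))
    list(
      summary = tibble(
        technique = tech,
        cdf_max_abs_diff = mean(cdfd),
        q25_diff = mean(purrr::map_dbl(qd, "q25")),
        q50_diff = mean(purrr::map_dbl(qd, "q50")),
        q75_diff = mean(purrr::map_dbl(qd, "q75")),
        ks_p_mean = ks$mean_p, ks_p_sd = ks$sd_p,
        mean_pct = mom$percent_diff[mom$moment == "mean"],
        variance_pct = mom$percent_diff[mom$moment == "variance"],
        skewness_pct = mom$percent_diff[mom$moment == "skewness"]
      ),
      avg_cdf = avg_cdf
    )
  })

  summary <- purrr::map_dfr(per_tech, "summary")
  crit <- dplyr::bind_rows(
    tibble(criterion = "cdf", technique = summary$technique,
           value = summary$cdf_max_abs_diff, direction = "lower"),
    tibble(criterion = "quartiles", technique = summary$technique,
           value = summary$q25_diff + summary$q50_diff + summary$q75_diff,
           direction = "lower"),
    tibble(criterion = "ks", technique = summary$technique,
           value = summary$ks_p_mean, direction = "higher"),
    tibble(criterion = "mean", technique = summary$technique,
           value = abs(summary$mean_pct), direction = "lower"),
    tibble(criterion = "variance", technique = summary$technique,
           value = abs(summary$variance_pct), direction = "lower"),
    tibble(criterion = "skewness", technique = summary$technique,
           value = abs(summary$skewness_pct), direction = "lower")
  )
  # the three-way ranking is defined for the full technique comparison only
  ranks <- if (length(techniques) == 3) rank_techniques(crit) else NULL

  cdf <- dplyr::bind_rows(
    tibble(technique = "original",
           empirical_cdf(original, bin_width, range = span)),
    purrr::imap_dfr(per_tech, function(pt, nm) tibble(technique = nm, pt$avg_cdf))
  )

  structure(list(summary = summary, ranks = ranks, cdf = cdf,
                 rate_percent = rate_percent, n_replicates = n_replicates,
                 bin_width = bin_width, seed = seed),
            class = "ppi_validation")
}

#' @export
print.ppi_validation <- function(x, ...) {
  cat(sprintf("Augmentation validation battery (rate %d%%, %d replicates)\n\n",
              x$rate_percent, x$n_replicates))
  print(x$summary)
  if (!is.null(x$ranks)) {
    cat("\nRanks (1 = best):\n")
    print(tidyr::pivot_wider(x$ranks[, c("criterion", "technique", "rank")],
                             names_from = "technique", values_from = "rank"))
  }
  invisible(x)
}
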