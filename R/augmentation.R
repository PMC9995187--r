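#' Interpolation samplers for minority-class oversampling
#'
#' `smote_sample()` draws a synthetic interval on the segment between an
#' anchor and a neighbor, `anchor + alpha * (neighbor - anchor)` with
#' `alpha` in `[0, 1]`. With anchors and neighbors resampled i.i.d. from the
#' data and `alpha ~ U(0, 1)` this construction preserves the mean but
#' shrinks the variance to 2/3 of the original.
#'
#' `modified_smote_sample()` rescales the interpolation step by the
#' variance-correction coefficient 3/2,
#' `anchor + (3/2) * alpha * (neighbor - anchor)`, which restores the
#' synthetic variance to the original (see [solve_variance_coefficient()]);
#' the draw may extrapolate past the neighbor by up to half the segment
#' length.
#'
#' @param anchor,neighbor Interval values in ms (vectorised).
#' @param alpha Interpolation fraction(s) in `[0, 1]`.
#' @return Synthetic interval value(s) in ms.
#' @export
#' @examples
#' smote_sample(180, 200, 0.5) # 190
#' modified_smote_sample(180, 200, 0.5) # 195
smote_sample <- function(anchor, neighbor, alpha) {
  check_alpha(alpha)
  anchor + alpha * (neighbor - anchor)
}

#' @rdname smote_sample
#' @export
modified_smote_sample <- function(anchor, neighbor, alpha) {
  check_alpha(alpha)
  anchor + smote_variance_coefficient * alpha * (neighbor - anchor)
}

smote_variance_coefficient <- 3 / 2

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || anyNA(alpha) || any(alpha < 0 | alpha > 1)) {
    ppi_abort("`alpha` must lie in [0, 1].")
  }
  invisible(alpha)
}

#' Variance-correction coefficient for interpolation oversampling
#'
#' For i.i.d. data X and `alpha ~ U(0, 1)`, a synthetic draw
#' `S = (1 - c*alpha) X_j + c*alpha X_k` has
#' `Var(S) = (1 - c + 2*c^2/3) * Var(X)`. Classic SMOTE (`c = 1`) therefore
#' shrinks the variance to 2/3; the unique positive `c` restoring
#' `Var(S) = Var(X)` is `c = 3/2`. Both the closed form and a numeric root of
#' the moment equation are returned for self-verification.
#'
#' @return A list with `closed_form` (3/2), `numeric_root` (root of
#'   `1 - c + 2c^2/3 = 1` found numerically), and `variance_ratio(c)`, the
#'   moment expression itself (so `variance_ratio(1)` gives the 2/3
#'   shrinkage).
#' @export
#' @examples
#' solve_variance_coefficient()$closed_form
solve_variance_coefficient <- function() {
  variance_ratio <- function(c) 1 - c + (2 / 3) * c^2
  # roots of 1 - c + 2c^2/3 = 1 are c = 0 and c = 3/2; bracket the positive one
  root <- uniroot(function(c) variance_ratio(c) - 1,
                  interval = c(0.5, 10), tol = 1e-15)$root
  list(closed_form = 3 / 2, numeric_root = root, variance_ratio = variance_ratio)
}

#' Smoothed-bootstrap sampler
#'
#' Resampling with replacement plus a random Gaussian kernel shift: each draw
#' is `X_j + h * Z` with `X_j` resampled from `data`, `Z ~ N(0, 1)` and `h`
#' the kernel bandwidth. Bandwidth 0 degenerates to the classic bootstrap
#' (a draw from the step-function empirical distribution); a positive
#' bandwidth renders the sampling distribution continuous with variance
#' inflated by `h^2`.
#'
#' @param data Non-empty numeric vector of intervals (ms).
#' @param bandwidth Kernel bandwidth `h >= 0` in ms; default Silverman's
#'   rule-of-thumb ([silverman_bandwidth()]).
#' @param n Number of draws.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of `n` synthetic intervals.
#' @export
smoothed_bootstrap_sample <- function(data, bandwidth = silverman_bandwidth(data),
                                      n = 1, seed = NULL) {
  if (length(data) == 0L || !is.numeric(data)) {
    ppi_abort("`data` must be a non-empty numeric vector.")
  }
  stopifnot_scalar_number(bandwidth, "bandwidth")
  if (bandwidth < 0) ppi_abort("`bandwidth` must be >= 0.")
  with_opt_seed(seed, {
    data[sample.int(length(data), n, replace = TRUE)] + bandwidth * rnorm(n)
  })
}

#' Silverman rule-of-thumb bandwidth
#'
#' Gaussian-kernel bandwidth `0.9 * min(sd, IQR/1.34) * n^(-1/5)` as
#' implemented by [stats::bw.nrd0()]; collapses to 0 for constant data so the
#' smoothed bootstrap degenerates gracefully to the classic bootstrap.
#'
#' @param data Numeric vector.
#' @return Bandwidth in ms.
#' @export
silverman_bandwidth <- function(data) {
  if (length(data) < 2L || sd(data) == 0) return(0)
  stats::bw.nrd0(data)
}

#' Augmentation configuration
#'
#' @param technique `"smote"`, `"modified_smote"` or `"smoothed_bootstrap"`.
#' @param rate_percent Augmentation rate: a non-negative multiple of 100.
#'   `rate_percent / 100` synthetic series are generated per original
#'   minority record (so 200% on 5 records adds 10 series and 800% makes the
#'   minority dataset 9x its original size); 0 means no augmentation.
#' @param seed Integer seed fully determining all draws.
#' @param bounds_policy `"none"` keeps synthetic values even when they fall
#'   outside `(0, 300]` (the default: redrawing would break the samplers'
#'   moment contracts); `"redraw"` resamples anchor/neighbor/alpha until the
#'   value is in range, logging redraw counts.
#' @param neighbor_pool `"record"` draws SMOTE neighbors from the source
#'   record's own series (per-record generation); `"minority"` pools all
#'   original minority intervals.
#' @param kernel_bandwidth_rule `"silverman"` or `"fixed"` (smoothed
#'   bootstrap only).
#' @param fixed_bandwidth Bandwidth in ms when `kernel_bandwidth_rule = "fixed"`.
#' @param max_interval Ceiling used by the `"redraw"` policy.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(technique = c("smote", "modified_smote", "smoothed_bootstrap"),
                                rate_percent = 400, seed = 1,
                                bounds_policy = c("none", "redraw"),
                                neighbor_pool = c("record", "minority"),
                                kernel_bandwidth_rule = c("silverman", "fixed"),
                                fixed_bandwidth = NULL, max_interval = 300) {
  technique <- match.arg(technique)
  bounds_policy <- match.arg(bounds_policy)
  neighbor_pool <- match.arg(neighbor_pool)
  kernel_bandwidth_rule <- match.arg(kernel_bandwidth_rule)
  stopifnot_scalar_number(rate_percent, "rate_percent")
  if (rate_percent < 0 || rate_percent %% 100 != 0) {
    ppi_abort("`rate_percent` must be a non-negative multiple of 100.")
  }
  if (kernel_bandwidth_rule == "fixed") {
    stopifnot_scalar_number(fixed_bandwidth, "fixed_bandwidth")
    if (fixed_bandwidth < 0) ppi_abort("`fixed_bandwidth` must be >= 0.")
  }
  structure(list(technique = technique, rate_percent = rate_percent,
                 seed = seed, bounds_policy = bounds_policy,
                 neighbor_pool = neighbor_pool,
                 kernel_bandwidth_rule = kernel_bandwidth_rule,
                 fixed_bandwidth = fixed_bandwidth,
                 max_interval = max_interval),
            class = "augmentation_config")
}

# Generate `n_out` synthetic intervals from one source series.
# `pool` and `pool_is_source` implement the neighbor rule: the neighbor is
# drawn uniformly from the pool excluding the anchor *instance* (k = N - 1
# neighborhood: the whole dataset rather than a local one).
draw_synthetic_intervals <- function(source_intervals, n_out, technique,
                                     pool, pool_anchor_idx, bandwidth,
                                     bounds_policy, max_interval) {
  draw_one <- function() {
    if (technique == "smoothed_bootstrap") {
      j <- sample.int(length(source_intervals), 1L)
      return(source_intervals[j] + bandwidth * rnorm(1))
    }
    a_local <- sample.int(length(source_intervals), 1L)
    anchor <- source_intervals[a_local]
    excl <- pool_anchor_idx[a_local]
    nb_idx <- sample.int(length(pool) - 1L, 1L)
    if (nb_idx >= excl) nb_idx <- nb_idx + 1L
    alpha <- runif(1)
    if (technique == "smote") smote_sample(anchor, pool[nb_idx], alpha)
    else modified_smote_sample(anchor, pool[nb_idx], alpha)
  }
  redraws <- 0L
  out <- vapply(seq_len(n_out), function(i) {
    val <- draw_one()
    if (bounds_policy == "redraw") {
      attempts <- 0L
      while (val <= 0 || val > max_interval) {
        attempts <- attempts + 1L
        if (attempts > 1000L) {
          ppi_abort("Redraw policy failed to find an in-range synthetic interval after 1000 attempts.")
        }
        val <- draw_one()
      }
      redraws <<- redraws + attempts
    }
    val
  }, numeric(1))
  attr(out, "redraws") <- redraws
  out
}

#' Generate one synthetic series from a source record
#'
#' Implements the per-record generation protocol: an anchor interval is
#' randomly selected from the source series and used to generate one
#' synthetic interval (by the configured sampler), repeated until the
#' synthetic series matches the length of the source series.
#'
#' @param x A cohort tibble containing the source record.
#' @param source_record_id Which record to generate from.
#' @param config An [augmentation_config()].
#' @param replicate Replicate index, used to build the deterministic
#'   synthetic record id `<source>.syn<replicate>`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A one-record cohort tibble with `provenance = "synthetic"`.
#' @export
augment_series <- function(x, source_record_id, config, replicate = 1L,
                           seed = NULL) {
  x <- validate_cohort(x)
  if (!inherits(config, "augmentation_config")) {
    ppi_abort("`config` must come from augmentation_config().")
  }
  rows <- x[x$record_id == source_record_id, ]
  if (nrow(rows) == 0L) {
    ppi_abort(sprintf("Record '%s' not found in cohort.", source_record_id))
  }
  src <- rows$interval_ms
  needs_pair <- config$technique %in% c("smote", "modified_smote")
  if (needs_pair && length(src) < 2L) {
    ppi_abort(sprintf("Record '%s' has fewer than 2 intervals; SMOTE-type samplers need an anchor and a distinct neighbor.",
                      source_record_id))
  }
  if (config$neighbor_pool == "minority" && needs_pair) {
    minority <- minority_class(x)
    pool_tbl <- dplyr::filter(x, .data$mechanism == minority,
                              .data$provenance == "original")
    pool <- pool_tbl$interval_ms
    pool_anchor_idx <- which(pool_tbl$record_id == source_record_id)
  } else {
    pool <- src
    pool_anchor_idx <- seq_along(src)
  }
  bandwidth <- if (config$technique != "smoothed_bootstrap") 0 else
    if (config$kernel_bandwidth_rule == "fixed") config$fixed_bandwidth else
      silverman_bandwidth(src)
  with_opt_seed(seed, {
    vals <- draw_synthetic_intervals(src, length(src), config$technique,
                                     pool, pool_anchor_idx, bandwidth,
                                     config$bounds_policy, config$max_interval)
    out <- tibble(
      record_id = rep(sprintf("%s.syn%02d", source_record_id, replicate), length(vals)),
      mechanism = rows$mechanism[1],
      interval_ms = as.numeric(vals),
      provenance = "synthetic",
      technique = config$technique,
      source_record_id = source_record_id
    )
    if (config$bounds_policy == "redraw") {
      attr(out, "redraws") <- attr(vals, "redraws")
    }
    out
  })
}

minority_class <- function(x) {
  counts <- x %>%
    dplyr::filter(.data$provenance == "original") %>%
    dplyr::distinct(.data$record_id, .data$mechanism) %>%
    dplyr::count(.data$mechanism)
  if (nrow(counts) == 0L) ppi_abort("Cohort has no original records.")
  counts$mechanism[which.min(counts$n)]
}

#' Augment the minority class of a cohort
#'
#' Adds `rate_percent / 100` synthetic series per original minority-class
#' record, each the same length as its source and generated by the configured
#' sampler. Original series are never modified, reordered or dropped; the
#' majority class is untouched. The full set of draws is determined by
#' `config$seed`.
#'
#' @param x A cohort tibble.
#' @param config An [augmentation_config()]; `rate_percent = 0` returns the
#'   cohort unchanged.
#' @return The input cohort with synthetic rows appended. The number of
#'   redraws (under `bounds_policy = "redraw"`) is attached as attribute
#'   `"redraws"`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_fafl = 2, n_mafl = 5), seed = 1)
#' aug <- augment_cohort(co, augmentation_config("modified_smote", 200, seed = 7))
#' cohort_summary(aug)$classes
augment_cohort <- function(x, config) {
  x <- validate_cohort(x)
  if (!inherits(config, "augmentation_config")) {
    ppi_abort("`config` must come from augmentation_config().")
  }
  if (config$rate_percent == 0) return(x)
  minority <- minority_class(x)
  sources <- x %>%
    dplyr::filter(.data$provenance == "original", .data$mechanism == minority) %>%
    dplyr::distinct(.data$record_id) %>%
    dplyr::pull(.data$record_id)
  if (length(sources) == 0L) ppi_abort("Cohort has no original minority-class series to augment.")
  n_rep <- config$rate_percent %/% 100L
  grid <- tidyr::expand_grid(source = sources, replicate = seq_len(n_rep))
  total_redraws <- 0L
  synthetic <- withr::with_seed(config$seed, {
    purrr::map2_dfr(grid$source, grid$replicate, function(s, r) {
      series <- augment_series(x, s, config, replicate = r, seed = NULL)
      total_redraws <<- total_redraws + (attr(series, "redraws") %||% 0L)
      series
    })
  })
  out <- validate_cohort(dplyr::bind_rows(x, synthetic))
  if (config$bounds_policy == "redraw") attr(out, "redraws") <- total_redraws
  out
}
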