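# ggplot2 graphics for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot interval series of a cohort
#'
#' One panel per mechanism, one line per record: interval duration against
#' interval index. The focal panel is expected to show visibly larger
#' interval-to-interval variability than the macroreentrant one.
#'
#' @param x A cohort tibble.
#' @param max_records Cap on the number of records drawn per mechanism.
#' @return A ggplot object.
#' @export
plot_cohort <- function(x, max_records = 10) {
  x <- validate_cohort(x)
  keep <- x %>%
    dplyr::distinct(.data$record_id, .data$mechanism) %>%
    dplyr::group_by(.data$mechanism) %>%
    dplyr::slice_head(n = max_records) %>%
    dplyr::pull(.data$record_id)
  x %>%
    dplyr::filter(.data$record_id %in% keep) %>%
    dplyr::group_by(.data$record_id) %>%
    dplyr::mutate(index = dplyr::row_number()) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$index, y = .data$interval_ms,
                                 group = .data$record_id,
                                 colour = .data$provenance)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~mechanism, scales = "free_x") +
    ggplot2::labs(x = "interval index", y = "P-P interval (ms)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot ppi_validation
#' @export
autoplot.ppi_validation <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(x = .data$edge, y = .data$cum_frac,
                               colour = .data$technique)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "P-P interval (ms)", y = "cumulative fraction",
                  colour = NULL,
                  title = sprintf("Average empirical CDF at %d%% augmentation",
                                  object$rate_percent)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ppi_rate_selection
#' @export
autoplot.ppi_rate_selection <- function(object, ...) {
  avg <- dplyr::bind_cols(tibble(rate_percent = NA_real_), object$average_curve)
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$length, y = .data$specificity,
                               colour = factor(.data$rate_percent))) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = avg, colour = "black", linetype = "dashed",
                       linewidth = 1) +
    ggplot2::labs(x = "feature combination length", y = "max specificity (%)",
                  colour = "rate (%)",
                  title = sprintf("Best rate: %d%% (dashed = average curve)",
                                  object$best_rate_percent)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ppi_scores
#' @export
autoplot.ppi_scores <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = stats::reorder(.data$feature, .data$score),
                               y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "wrapper score",
                  title = sprintf("Wrapper feature scores (%s)",
                                  toupper(object$classifier))) +
    ggplot2::theme_minimal()
}

#' @method autoplot ppi_performance
#' @export
autoplot.ppi_performance <- function(object, ...) {
  object$per_fold %>%
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity"),
                        names_to = "metric", values_to = "percent") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$metric, y = .data$percent)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "percent",
                  title = sprintf("Per-fold metrics (%s, %d-fold CV)",
                                  toupper(object$classifier), object$k)) +
    ggplot2::theme_minimal()
}
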