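# broom-style tidiers for the package's result objects.

#' Tidy a cross-validated performance report
#'
#' @param x A `ppi_performance` object from [evaluate_classifier()].
#' @param ... Unused.
#' @return Per-fold confusion counts and metrics as a tibble.
#' @method tidy ppi_performance
#' @export
tidy.ppi_performance <- function(x, ...) {
  dplyr::bind_cols(tibble(classifier = x$classifier), x$per_fold)
}

#' @rdname tidy.ppi_performance
#' @return `glance()` returns the one-row fold-mean summary.
#' @method glance ppi_performance
#' @export
glance.ppi_performance <- function(x, ...) x$summary

#' Tidy an augmentation validation report
#'
#' @param x A `ppi_validation` object from [validate_augmentation()].
#' @param ... Unused.
#' @return The per-criterion rank table as a tibble.
#' @method tidy ppi_validation
#' @export
tidy.ppi_validation <- function(x, ...) x$ranks

#' @rdname tidy.ppi_validation
#' @return `glance()` returns the per-technique replicate-averaged summary.
#' @method glance ppi_validation
#' @export
glance.ppi_validation <- function(x, ...) x$summary

#' Tidy wrapper feature scores
#'
#' @param x A `ppi_scores` object from [wrapper_scores()].
#' @param ... Unused.
#' @return The per-feature score table as a tibble.
#' @method tidy ppi_scores
#' @export
tidy.ppi_scores <- function(x, ...) x$scores

#' Tidy a combined feature relevance table
#'
#' @param x A `ppi_score_table` object from [feature_score_table()].
#' @param ... Unused.
#' @return The relevance table as a tibble.
#' @method tidy ppi_score_table
#' @export
tidy.ppi_score_table <- function(x, ...) x$table

#' Tidy a rate-selection result
#'
#' @param x A `ppi_rate_selection` object from [select_best_rate()].
#' @param ... Unused.
#' @return The per-rate distance table as a tibble.
#' @method tidy ppi_rate_selection
#' @export
tidy.ppi_rate_selection <- function(x, ...) x$distances

#' @rdname tidy.ppi_rate_selection
#' @return `glance()` returns a one-row tibble with the selected rate.
#' @method glance ppi_rate_selection
#' @export
glance.ppi_rate_selection <- function(x, ...) {
  tibble(best_rate_percent = x$best_rate_percent,
         min_distance = min(x$distances$distance))
}
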