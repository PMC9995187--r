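#' Build a cohort of P-P interval series
#'
#' A cohort is stored in long format: one row per measured P-to-P interval,
#' with the record it belongs to, its mechanism label, and provenance
#' metadata distinguishing original clinical series from synthetic series
#' produced by data augmentation.
#'
#' @param record_id Character vector, one entry per interval; intervals
#'   sharing a `record_id` form one series and keep their row order.
#' @param mechanism Mechanism label per interval, `"FAFL"` (focal) or
#'   `"MAFL"` (macroreentrant); must be constant within a record.
#' @param interval_ms Interval durations in milliseconds, strictly positive.
#' @param provenance `"original"` or `"synthetic"` per interval.
#' @param technique Augmentation technique that produced a synthetic series
#'   (`"none"` for original series).
#' @param source_record_id For synthetic series, the original record the
#'   series was generated from; `NA` for original series.
#'
#' @return A tibble with columns `record_id`, `mechanism`, `interval_ms`,
#'   `provenance`, `technique`, `source_record_id`, validated against the
#'   cohort invariants.
#' @export
#' @examples
#' cohort(
#'   record_id = rep(c("r1", "r2"), each = 3),
#'   mechanism = rep(c("FAFL", "MAFL"), each = 3),
#'   interval_ms = c(231, 245, 228, 250, 251, 249)
#' )
cohort <- function(record_id, mechanism, interval_ms,
                   provenance = "original", technique = "none",
                   source_record_id = NA_character_) {
  x <- tibble(
    record_id = as.character(record_id),
    mechanism = as.character(mechanism),
    interval_ms = as.numeric(interval_ms),
    provenance = as.character(provenance),
    technique = as.character(technique),
    source_record_id = as.character(source_record_id)
  )
  validate_cohort(x)
}

cohort_cols <- c("record_id", "mechanism", "interval_ms", "provenance",
                 "technique", "source_record_id")

#' Validate a cohort tibble
#'
#' Checks the invariants every pipeline stage relies on: positive intervals,
#' known mechanism labels, one label per record, and consistency between
#' provenance, technique and source record (a series is synthetic if and only
#' if its technique is set and it names the record it was generated from).
#'
#' @param x A data frame in cohort long format.
#' @return `x` as a tibble, invisibly unchanged, or a validation error naming
#'   the offending record or row.
#' @export
validate_cohort <- function(x) {
  if (!is.data.frame(x)) ppi_abort("A cohort must be a data frame.")
  missing_cols <- setdiff(cohort_cols, names(x))
  if (length(missing_cols)) {
    ppi_abort(sprintf("Cohort is missing columns: %s.",
                      paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)[, cohort_cols]
  if (nrow(x) == 0L) return(x)

  bad <- which(!is.finite(x$interval_ms))
  if (length(bad)) {
    ppi_abort(sprintf("Non-numeric interval at row %d (record '%s').",
                      bad[1], x$record_id[bad[1]]))
  }
  # measured series must be strictly positive; synthetic series may carry
  # rare out-of-range extrapolations when bounds_policy = "none" (clamping
  # or redrawing them would break the samplers' variance contracts)
  bad <- which(x$interval_ms <= 0 & x$provenance == "original")
  if (length(bad)) {
    ppi_abort(sprintf("Non-positive interval at row %d (record '%s').",
                      bad[1], x$record_id[bad[1]]))
  }
  bad <- which(!x$mechanism %in% mechanism_levels)
  if (length(bad)) {
    ppi_abort(sprintf("Unknown mechanism label '%s' at row %d (record '%s').",
                      x$mechanism[bad[1]], bad[1], x$record_id[bad[1]]))
  }
  bad <- which(!x$technique %in% technique_levels)
  if (length(bad)) {
    ppi_abort(sprintf("Unknown technique '%s' at row %d.", x$technique[bad[1]], bad[1]))
  }
  bad <- which(!x$provenance %in% c("original", "synthetic"))
  if (length(bad)) {
    ppi_abort(sprintf("Unknown provenance '%s' at row %d.", x$provenance[bad[1]], bad[1]))
  }

  meta <- dplyr::distinct(x, .data$record_id, .data$mechanism, .data$provenance,
                          .data$technique, .data$source_record_id)
  dup <- meta$record_id[duplicated(meta$record_id)]
  if (length(dup)) {
    ppi_abort(sprintf("Record '%s' has conflicting labels or metadata across rows.", dup[1]))
  }

  src <- ifelse(is.na(meta$source_record_id) | meta$source_record_id == "",
                NA_character_, meta$source_record_id)
  is_syn <- meta$provenance == "synthetic"
  inconsistent <- is_syn != (meta$technique != "none") | is_syn != !is.na(src)
  if (any(inconsistent)) {
    ppi_abort(sprintf(
      "Record '%s': provenance, technique and source_record_id disagree (synthetic series need technique and source; original series need neither).",
      meta$record_id[which(inconsistent)[1]]))
  }
  x$source_record_id <- ifelse(is.na(x$source_record_id) | x$source_record_id == "",
                               NA_character_, x$source_record_id)
  x
}

#' Remove implausibly long intervals from a cohort
#'
#' Intervals longer than `max_interval` are taken to be false intervals not
#' separating two consecutive P-waves (e.g. spanning an undetected wave) and
#' are dropped; intervals exactly at the ceiling are kept. Row order and all
#' metadata are preserved, and the operation is idempotent.
#'
#' @param x A cohort tibble (see [cohort()]).
#' @param max_interval Ceiling in milliseconds; default 300 ms.
#' @return The cohort with offending interval rows removed. Records whose
#'   intervals are all removed disappear from the long format entirely.
#' @export
#' @examples
#' co <- cohort("r1", "FAFL", c(250, 310, 180))
#' filter_intervals(co)
filter_intervals <- function(x, max_interval = 300) {
  x <- validate_cohort(x)
  stopifnot_scalar_number(max_interval, "max_interval", positive = TRUE)
  dplyr::filter(x, .data$interval_ms <= max_interval)
}

#' Convert P-wave peak times to interval series
#'
#' Plumbing between an upstream P-wave peak detector and the interval-series
#' pipeline: successive differences of the peak timestamps.
#'
#' @param peak_times Strictly increasing numeric vector of peak times in
#'   milliseconds from record start.
#' @return Numeric vector of interval durations (length `length(peak_times) - 1`).
#' @export
#' @examples
#' peaks_to_intervals(c(0, 200, 450))
peaks_to_intervals <- function(peak_times) {
  if (!is.numeric(peak_times) || anyNA(peak_times)) {
    ppi_abort("`peak_times` must be numeric without missing values.")
  }
  if (length(peak_times) <= 1L) return(numeric(0))
  d <- diff(peak_times)
  if (any(d <= 0)) {
    ppi_abort(sprintf("`peak_times` must be strictly increasing (violation at position %d).",
                      which(d <= 0)[1] + 1L))
  }
  d
}

#' Read / write cohort files
#'
#' Cohorts are serialized either as long-format CSV (one row per interval,
#' columns `record_id`, `mechanism`, `interval_ms`, `provenance`, `technique`,
#' `source_record_id`) or as JSON (one object per series with an `intervals`
#' array). `read_cohort(write_cohort(x))` round-trips values at full
#' precision.
#'
#' @param x A cohort tibble.
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @return `read_cohort()` returns a validated cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    if (file.size(path) == 0L) return(empty_cohort())
    # readr warns on parse problems; they are re-raised as classed errors below
    x <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
      record_id = readr::col_character(),
      mechanism = readr::col_character(),
      interval_ms = readr::col_double(),
      provenance = readr::col_character(),
      technique = readr::col_character(),
      source_record_id = readr::col_character()
    ), progress = FALSE))
    prob <- readr::problems(x)
    if (nrow(prob)) {
      ppi_abort(sprintf("Malformed value in '%s' at file row %d: expected %s.",
                        path, prob$row[1], prob$expected[1]))
    }
    if (nrow(x) == 0L) return(empty_cohort())
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) return(empty_cohort())
    recs <- jsonlite::fromJSON(txt, simplifyDataFrame = FALSE)
    if (length(recs) == 0L) return(empty_cohort())
    x <- purrr::map_dfr(recs, function(r) {
      tibble(
        record_id = as.character(r$record_id),
        mechanism = as.character(r$mechanism),
        interval_ms = as.numeric(unlist(r$intervals)),
        provenance = as.character(r$provenance %||% "original"),
        technique = as.character(r$technique %||% "none"),
        source_record_id = as.character(r$source_record_id %||% NA_character_)
      )
    })
  }
  validate_cohort(x)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(x, path, format = c("auto", "csv", "json")) {
  x <- validate_cohort(x)
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    out <- lapply(unique(x$record_id), function(id) {
      rows <- x[x$record_id == id, ]
      list(record_id = id, mechanism = rows$mechanism[1],
           provenance = rows$provenance[1], technique = rows$technique[1],
           source_record_id = rows$source_record_id[1],
           intervals = rows$interval_ms)
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else
    ppi_abort(sprintf("Cannot infer format from extension '.%s'; pass `format`.", ext))
}

empty_cohort <- function() {
  tibble(record_id = character(), mechanism = character(),
         interval_ms = numeric(), provenance = character(),
         technique = character(), source_record_id = character())
}

#' Summarise a cohort by record and by class
#'
#' @param x A cohort tibble.
#' @return A list with `records` (one row per series: interval count, mean,
#'   SD) and `classes` (per-mechanism record counts, for original series, plus
#'   the imbalance ratio majority/minority).
#' @export
cohort_summary <- function(x) {
  x <- validate_cohort(x)
  records <- x %>%
    dplyr::group_by(.data$record_id, .data$mechanism, .data$provenance,
                    .data$technique) %>%
    dplyr::summarise(n_intervals = dplyr::n(),
                     mean_ms = mean(.data$interval_ms),
                     sd_ms = sd(.data$interval_ms), .groups = "drop")
  classes <- records %>%
    dplyr::count(.data$mechanism, .data$provenance, name = "n_records")
  orig <- dplyr::filter(classes, .data$provenance == "original")
  ratio <- if (nrow(orig) >= 2) max(orig$n_records) / min(orig$n_records) else NA_real_
  list(records = records, classes = classes, imbalance_ratio = ratio)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
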