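test_that("interval filtering drops only intervals above the ceiling, in place", {
  co <- cohort("r1", "FAFL", c(250, 310, 180))
  expect_equal(filter_intervals(co)$interval_ms, c(250, 180))

  # exactly-300 sits at the boundary and is kept; only strictly-above goes
  co <- cohort("r1", "FAFL", c(300, 300.5))
  expect_equal(filter_intervals(co)$interval_ms, 300)

  expect_equal(nrow(filter_intervals(cohort(character(), character(), numeric()))), 0L)

  # metadata of surviving rows untouched, and the filter is idempotent
  co <- cohort(rep(c("a", "b"), each = 3), rep(c("FAFL", "MAFL"), each = 3),
               c(100, 400, 200, 280, 301, 299))
  once <- filter_intervals(co)
  expect_equal(filter_intervals(once), once)
  expect_equal(once$record_id, c("a", "a", "b", "b"))
  expect_equal(once$mechanism, c("FAFL", "FAFL", "MAFL", "MAFL"))
})

test_that("peak timestamps convert to first-difference intervals and back", {
  expect_equal(peaks_to_intervals(c(0, 200, 450)), c(200, 250))
  expect_equal(peaks_to_intervals(100), numeric(0))
  expect_error(peaks_to_intervals(c(0, 100, 100)), class = "flutterppi_error")

  # cumulative sum anchored at the first peak reconstructs the input exactly
  withr::with_seed(9, {
    for (i in 1:20) {
      peaks <- cumsum(c(runif(1, 0, 50), runif(sample(2:30, 1), 1, 400)))
      expect_identical(c(peaks[1], peaks[1] + cumsum(peaks_to_intervals(peaks))),
                       peaks)
    }
  })
})

test_that("cohort validation rejects malformed inputs with the offender named", {
  expect_error(cohort("r1", "XAFL", 100), "XAFL", class = "flutterppi_error")
  expect_error(cohort("r1", "FAFL", -5), "r1", class = "flutterppi_error")
  # one record, two mechanism labels
  expect_error(cohort(c("r1", "r1"), c("FAFL", "MAFL"), c(100, 110)),
               "conflicting", class = "flutterppi_error")
  # synthetic provenance without technique/source is inconsistent
  expect_error(
    cohort("s1", "FAFL", 100, provenance = "synthetic"),
    "disagree", class = "flutterppi_error"
  )
})

test_that("class counts aggregate per-series membership and set the imbalance ratio", {
  co <- dplyr::bind_rows(
    cohort(rep(c("f1", "f2"), each = 2), "FAFL", c(220, 230, 210, 215)),
    cohort(rep(sprintf("m%d", 1:8), each = 2), "MAFL", rep(c(250, 251), 8))
  )
  cs <- cohort_summary(co)
  expect_equal(cs$classes$n_records[cs$classes$mechanism == "FAFL"], 2L)
  expect_equal(cs$classes$n_records[cs$classes$mechanism == "MAFL"], 8L)
  expect_equal(cs$imbalance_ratio, 4)
  expect_equal(sum(cs$records$n_intervals), nrow(co))
})

test_that("cohort files round-trip exactly in both formats", {
  co <- dplyr::bind_rows(
    toy_cohort(),
    cohort("f1.syn01", "FAFL", c(214.000244140625, 233.5),
           provenance = "synthetic", technique = "modified_smote",
           source_record_id = "f1")
  )
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_cohort(co, path)
    expect_equal(read_cohort(path), co)
  }
})

test_that("malformed and empty cohort files are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,mechanism,interval_ms,provenance,technique,source_record_id",
               "r1,XAFL,100,original,none,"), path)
  expect_error(read_cohort(path), "XAFL", class = "flutterppi_error")

  writeLines(c("record_id,mechanism,interval_ms,provenance,technique,source_record_id",
               "r1,FAFL,abc,original,none,"), path)
  expect_error(read_cohort(path), class = "flutterppi_error")

  file.create(path2 <- withr::local_tempfile(fileext = ".csv"))
  expect_equal(nrow(read_cohort(path2)), 0L)
})
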