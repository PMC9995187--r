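test_that("interpolation samplers follow their defining formulas", {
  expect_equal(smote_sample(180, 200, 0.5), 190)
  expect_equal(smote_sample(180, 200, 0), 180)
  expect_equal(modified_smote_sample(180, 200, 0.5), 195)
  expect_equal(modified_smote_sample(180, 200, 1), 210) # 1.5x the difference
  expect_error(smote_sample(180, 200, 1.2), class = "flutterppi_error")
  expect_error(modified_smote_sample(180, 200, -0.1), class = "flutterppi_error")

  # a SMOTE draw stays on the closed segment; modified may overshoot by <= 50%
  withr::with_seed(3, {
    a <- runif(500, 100, 300); b <- runif(500, 100, 300); al <- runif(500)
    s <- smote_sample(a, b, al)
    expect_true(all(s >= pmin(a, b) & s <= pmax(a, b)))
    m <- modified_smote_sample(a, b, al)
    expect_true(all(abs(m - a) <= 1.5 * abs(b - a) + 1e-12))
  })
})

test_that("the variance-correction coefficient is 3/2 and SMOTE's shrinkage 2/3", {
  sol <- solve_variance_coefficient()
  expect_identical(sol$closed_form, 1.5)
  expect_lt(abs(sol$numeric_root - sol$closed_form), 1e-12)
  expect_equal(sol$variance_ratio(1), 2 / 3)
  expect_equal(sol$variance_ratio(3 / 2), 1)
})

test_that("smoothed bootstrap preserves the mean and inflates variance by h^2", {
  expect_equal(smoothed_bootstrap_sample(rep(200, 5), bandwidth = 0, n = 10, seed = 1),
               rep(200, 10))
  expect_error(smoothed_bootstrap_sample(numeric(0)), class = "flutterppi_error")

  x <- withr::with_seed(11, rnorm(2000, 240, 20))
  h <- 6
  draws <- smoothed_bootstrap_sample(x, bandwidth = h, n = 1e5, seed = 2)
  expect_equal(mean(draws), mean(x), tolerance = 0.002)
  # resampling draws from the empirical (n-denominator) distribution
  m2 <- mean((x - mean(x))^2)
  expect_equal(var(draws), m2 + h^2, tolerance = 0.02)
})

test_that("Silverman bandwidth matches the reference rule and degenerates to 0", {
  x <- withr::with_seed(5, rnorm(100, 200, 15))
  expect_equal(silverman_bandwidth(x), stats::bw.nrd0(x))
  expect_equal(silverman_bandwidth(rep(7, 20)), 0)
})

test_that("per-record generation yields same-length, reproducible synthetic series", {
  co <- toy_cohort()
  cfg <- augmentation_config("smote", 100, seed = 5)
  s1 <- augment_series(co, "f1", cfg, replicate = 1, seed = 99)
  expect_equal(nrow(s1), 4L) # matches the source series length
  expect_equal(unique(s1$provenance), "synthetic")
  expect_equal(unique(s1$technique), "smote")
  expect_equal(unique(s1$source_record_id), "f1")
  expect_identical(s1, augment_series(co, "f1", cfg, replicate = 1, seed = 99))

  # constant source + zero bandwidth -> constant synthetic series
  const <- cohort(rep("c1", 6), "FAFL", rep(210, 6))
  cfg_b <- augmentation_config("smoothed_bootstrap", 100,
                               kernel_bandwidth_rule = "fixed", fixed_bandwidth = 0)
  expect_equal(augment_series(const, "c1", cfg_b, seed = 1)$interval_ms, rep(210, 6))

  short <- cohort("s", "FAFL", 150)
  expect_error(augment_series(short, "s", cfg), "s", class = "flutterppi_error")
})

test_that("cohort augmentation implements the rate protocol exactly", {
  co <- generate_cohort(cohort_spec(n_fafl = 5, n_mafl = 8,
                                    intervals_min = 10, intervals_max = 20),
                        seed = 4)
  aug <- augment_cohort(co, augmentation_config("modified_smote", 200, seed = 2))
  syn <- dplyr::distinct(aug[aug$provenance == "synthetic", ],
                         record_id, mechanism, source_record_id)
  expect_equal(nrow(syn), 10L) # 5 minority records x rate 200%
  expect_true(all(syn$mechanism == "FAFL"))

  # originals pass through untouched, in order
  expect_identical(aug[seq_len(nrow(co)), ], co)

  # rate 0 is the identity
  expect_identical(augment_cohort(co, augmentation_config("smote", 0)), co)

  # full determinism from the config seed
  cfg <- augmentation_config("smoothed_bootstrap", 300, seed = 123)
  expect_identical(augment_cohort(co, cfg), augment_cohort(co, cfg))

  expect_error(augmentation_config("smote", 150), class = "flutterppi_error")
})

test_that("samplers keep the mean and hit their variance contracts on series draws", {
  co <- cohort(rep("f1", 60), "FAFL", withr::with_seed(8, rnorm(60, 230, 18)))
  src <- co$interval_ms
  m2 <- mean((src - mean(src))^2) # anchors resample the empirical distribution
  draws <- function(tech) {
    cfg <- augmentation_config(tech, 100, seed = 31)
    unlist(lapply(1:300, function(r) augment_series(co, "f1", cfg, r, seed = 4000 + r)$interval_ms))
  }
  for (tech in c("smote", "modified_smote", "smoothed_bootstrap")) {
    d <- draws(tech)
    expect_equal(mean(d), mean(src), tolerance = 0.005)
  }
  expect_equal(var(draws("smote")) / m2, 2 / 3, tolerance = 0.05)
  expect_equal(var(draws("modified_smote")) / m2, 1, tolerance = 0.05)
  h <- silverman_bandwidth(src)
  expect_equal(var(draws("smoothed_bootstrap")), m2 + h^2, tolerance = 0.05)
})

test_that("the redraw bounds policy keeps synthetic intervals in range and counts redraws", {
  co <- cohort(rep("f1", 12), "FAFL", c(rep(295, 6), rep(120, 6)))
  cfg <- augmentation_config("modified_smote", 800, seed = 6, bounds_policy = "redraw")
  aug <- augment_cohort(co, cfg)
  syn <- aug$interval_ms[aug$provenance == "synthetic"]
  expect_true(all(syn > 0 & syn <= 300))
  expect_gte(attr(aug, "redraws"), 1L) # this geometry must overshoot sometimes
})
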