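test_that("missing heart rate nulls the matching step counts only", {
  s <- make_samples(times = as.POSIXct("2022-01-01 10:00:00", tz = "UTC") + c(0, 60, 120),
                    steps = c(5L, 7L, 9L),
                    heart_rate = c(70, NA, 80))
  out <- nullify_missing_hr(s)
  expect_identical(out$steps, c(5L, NA, 9L))
  expect_identical(out[c(1, 3), ], s[c(1, 3), ])

  none_missing <- make_samples(times = as.POSIXct("2022-01-01", tz = "UTC") + 1:3,
                               steps = 1:3)
  expect_identical(nullify_missing_hr(none_missing), none_missing)

  all_missing <- make_samples(times = as.POSIXct("2022-01-01", tz = "UTC") + 1:3,
                              steps = 1:3, heart_rate = rep(NA_real_, 3))
  expect_true(all(is.na(nullify_missing_hr(all_missing)$steps)))
})

test_that("hourly aggregation sums steps and takes the median heart rate", {
  expect_identical(nrow(aggregate_hourly(make_samples(times = character(),
                                                      steps = integer())[0, ])), 0L)
  s <- make_samples(
    times = c("2022-01-01 10:05:00", "2022-01-01 10:20:00", "2022-01-01 11:10:00"),
    steps = c(30L, 50L, 20L),
    heart_rate = c(70, 90, 80))
  h <- aggregate_hourly(s)
  expect_identical(h$hour, c(10L, 11L))
  expect_identical(h$steps_sum, c(80, 20))

  s3 <- make_samples(times = paste("2022-01-01", c("09:01:00", "09:02:00", "09:03:00")),
                     steps = c(0L, 0L, 0L), heart_rate = c(70, 80, 90))
  expect_identical(aggregate_hourly(s3)$hr_median, 80)
})

test_that("an hour whose heart rates are all missing is nulled entirely", {
  s <- make_samples(
    times = paste("2022-01-01", c("09:01:00", "09:30:00", "10:15:00")),
    steps = c(10L, 20L, 30L),
    heart_rate = c(NA, NA, 75))
  h <- aggregate_hourly(s)
  expect_identical(h$steps_sum, c(NA_real_, 30))
  expect_identical(h$hr_median, c(NA_real_, 75))
  # without the hourly heart-rate rule the steps survive
  h2 <- aggregate_hourly(s, enforce_hr_rule = FALSE)
  expect_identical(h2$steps_sum, c(30, 30))
})

test_that("centered 3-point smoothing follows the edge and missing rules", {
  expect_equal(smooth_hourly(c(0, 3, 6)), c(1.5, 3, 4.5))
  expect_equal(smooth_hourly(rep(4, 10)), rep(4, 10))
  expect_equal(smooth_hourly(7), 7)
  expect_equal(smooth_hourly(numeric(0)), numeric(0))
  # missing values are skipped as neighbours and never imputed
  out <- smooth_hourly(c(1, NA, 7, 10))
  expect_equal(out, c(1, NA, 8.5, 8.5))
})

test_that("14 identical quiet-edged days reproduce the day's smoothed profile", {
  pattern <- c(rep(0, 7), 10, 40, 10, rep(0, 3), 30, 60, 30, rep(0, 3), 20, 50, 0, 0, 0)
  stopifnot(pattern[1] == 0, pattern[24] == 0)
  samples <- make_daily_pattern_samples(pattern, n_days = 14)
  hourly <- aggregate_hourly(samples)
  prof <- build_mean_profile(hourly, window_end = as.Date("2022-01-15"),
                             window_days = 30, min_days = 14)
  expect_identical(prof$n_days_used, 14L)
  # zero-valued edge hours make the day-boundary windows exact
  expect_equal(as.numeric(prof[paste0("hour_", 0:23)]),
               smooth_hourly(pattern))
})

test_that("patients with fewer than 14 days of data are excluded, not zeroed", {
  pattern <- c(rep(0, 9), rep(10, 6), rep(0, 9))
  samples <- make_daily_pattern_samples(pattern, n_days = 13)
  hourly <- aggregate_hourly(samples)
  err <- expect_error(
    build_mean_profile(hourly, window_end = as.Date("2022-01-20")),
    class = "watbarthel_insufficient_data")
  expect_identical(err$n_days_used, 13L)
  # 14 days pass
  ok <- build_mean_profile(aggregate_hourly(
    make_daily_pattern_samples(pattern, n_days = 14)),
    window_end = as.Date("2022-01-20"))
  expect_identical(ok$n_days_used, 14L)
})

test_that("profiles match a brute-force day/hour oracle", {
  # alternating 0/10 steps at hour 9: day-mean at hour 9 is 5 before smoothing
  days <- 20
  pattern0 <- rep(0, 24)
  times <- as.POSIXct(paste(as.Date("2022-03-01") + rep(seq_len(days) - 1, each = 24),
                            sprintf("%02d:30:00", rep(0:23, days))), tz = "UTC")
  steps <- rep(0L, days * 24)
  steps[(seq_len(days) - 1) * 24 + 10] <- rep(c(0L, 10L), days / 2)  # hour 9
  samples <- make_samples(times = times, steps = steps)
  hourly <- aggregate_hourly(samples)
  prof <- build_mean_profile(hourly, window_end = as.Date("2022-03-21"))
  raw_hour9 <- dplyr::filter(hourly, hour == 9)$steps_sum
  expect_equal(mean(raw_hour9), 5)
  oracle <- oracle_profile(samples, window_end = as.Date("2022-03-21"))
  expect_equal(as.numeric(prof[paste0("hour_", 0:23)]), oracle$values)
  expect_identical(prof$n_days_used, oracle$n_days_used)
})

test_that("the pipeline is insensitive to the order of input samples", {
  co <- generate_cohort(sim_config(n_patients = 3, days_recorded = 16, seed = 21,
                                   dropout_prob = 0))
  shuffled <- co$series[withr::with_seed(1, sample.int(nrow(co$series))), ]
  p1 <- preprocess_cohort(co$series, co$truth)
  p2 <- preprocess_cohort(shuffled, co$truth)
  expect_equal(p1$profiles, p2$profiles)
})

test_that("profiles agree with the oracle on random synthetic patients", {
  co <- generate_cohort(sim_config(n_patients = 50, days_recorded = 16,
                                   seed = 31, dropout_prob = 0.2,
                                   missing_hr_prob = 0.1))
  hourly <- aggregate_hourly(co$series)
  n_checked <- 0
  for (pid in unique(co$truth$patient_id)) {
    enc <- co$truth$encounter_date[co$truth$patient_id == pid]
    oracle <- oracle_profile(co$series[co$series$patient_id == pid, ], enc,
                             window_days = 30, min_days = 14)
    fitted <- tryCatch(
      build_mean_profile(hourly[hourly$patient_id == pid, ], enc),
      watbarthel_insufficient_data = function(e) NULL)
    expect_identical(is.null(fitted), is.null(oracle), info = pid)
    if (!is.null(fitted)) {
      expect_equal(as.numeric(fitted[paste0("hour_", 0:23)]), oracle$values,
                   info = pid)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 30)
})

test_that("profile values stay within physical bounds", {
  co <- generate_cohort(sim_config(n_patients = 10, days_recorded = 16, seed = 41,
                                   dropout_prob = 0))
  prep <- preprocess_cohort(co$series, co$truth)
  hourly <- aggregate_hourly(co$series)
  vals <- as.matrix(prep$profiles[, paste0("hour_", 0:23)])
  expect_true(all(vals >= 0, na.rm = TRUE))
  expect_lte(max(vals, na.rm = TRUE), max(hourly$steps_sum, na.rm = TRUE))
  expect_identical(ncol(vals), 24L)
})
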