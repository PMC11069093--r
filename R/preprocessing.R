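#' Null step counts wherever the heart rate is missing
#'
#' Quality-control rule applied to raw tracker samples: a sample without a
#' heart-rate reading is treated as "device not worn", so its step count is
#' set to missing as well. Order and number of samples are preserved.
#'
#' @param samples Tibble with `steps` and `heart_rate` columns.
#' @return The same tibble with `steps` set to `NA` where `heart_rate` is `NA`.
#' @export
nullify_missing_hr <- function(samples) {
  samples$steps[is.na(samples$heart_rate)] <- NA_integer_
  samples
}

#' Aggregate raw samples into hourly records
#'
#' Sums step counts and takes the median heart rate within each
#' (patient, calendar day, hour-of-day) interval. Missing values are skipped
#' inside an interval; an interval whose samples are all missing yields
#' missing aggregates. When `enforce_hr_rule` is `TRUE` (the default), an
#' hour whose median heart rate is missing has its step sum nulled too —
#' the hourly-granularity version of [nullify_missing_hr()].
#'
#' @param samples Tibble with `patient_id`, `timestamp`, `steps`,
#'   `heart_rate`.
#' @param tz Time zone in which the civil day and hour are read.
#' @param enforce_hr_rule Null `steps_sum` wherever `hr_median` is missing.
#' @return Tibble with `patient_id`, `date`, `hour`, `steps_sum`,
#'   `hr_median`, one row per interval holding at least one sample, sorted
#'   chronologically within patient.
#' @export
aggregate_hourly <- function(samples, tz = "UTC", enforce_hr_rule = TRUE) {
  out <- tibble::tibble(
    patient_id = character(), date = as.Date(character()),
    hour = integer(), steps_sum = numeric(), hr_median = numeric()
  )
  if (nrow(samples) == 0L) return(out)
  lt <- as.POSIXlt(samples$timestamp, tz = tz)
  samples |>
    dplyr::mutate(
      date = as.Date(format(lt, "%Y-%m-%d")),
      hour = lt$hour
    ) |>
    dplyr::group_by(.data$patient_id, .data$date, .data$hour) |>
    dplyr::summarise(
      steps_sum = if (all(is.na(.data$steps))) NA_real_
                  else as.numeric(sum(.data$steps, na.rm = TRUE)),
      hr_median = if (all(is.na(.data$heart_rate))) NA_real_
                  else stats::median(.data$heart_rate, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      steps_sum = ifelse(enforce_hr_rule & is.na(.data$hr_median),
                         NA_real_, .data$steps_sum)
    ) |>
    dplyr::arrange(.data$patient_id, .data$date, .data$hour)
}

#' Smooth an hourly series with a centered 3-point rolling mean
#'
#' Each value becomes the mean of the available (non-missing) values among
#' itself and its two chronological neighbours; the first and last entries
#' use the one neighbour they have. Missing entries stay missing — they are
#' skipped as neighbours, never imputed.
#'
#' @param x Numeric vector, chronologically ordered hourly step sums.
#' @param window Window size; only the centered 3-point window is supported.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' smooth_hourly(c(0, 3, 6)) # 1.5 3.0 4.5
smooth_hourly <- function(x, window = 3) {
  stopifnot("only the centered window of size 3 is supported" = window == 3)
  n <- length(x)
  if (n <= 1L) return(x)
  prev <- c(NA, x[-n])
  nxt <- c(x[-1], NA)
  num <- ifelse(is.na(prev), 0, prev) + ifelse(is.na(x), 0, x) +
    ifelse(is.na(nxt), 0, nxt)
  den <- (!is.na(prev)) + (!is.na(x)) + (!is.na(nxt))
  out <- ifelse(den > 0, num / den, NA_real_)
  out[is.na(x)] <- NA_real_  # no imputation of unworn hours
  out
}

#' Build one patient's mean 24-hour activity profile
#'
#' Restricts the hourly records to the `window_days`-day look-back window
#' ending the day before `window_end` (half-open
#' `[window_end - window_days, window_end)`), lays them on the full
#' day-by-hour grid, smooths the chronological hourly series with
#' [smooth_hourly()], and then averages the smoothed values by hour of day.
#' A patient contributes to the model only if at least `min_days` distinct
#' days in the window carry any non-missing step data; otherwise the patient
#' is excluded by signalling a condition of class
#' `watbarthel_insufficient_data` (never a silent all-zero profile).
#'
#' @param records Hourly records of a single patient, as produced by
#'   [aggregate_hourly()].
#' @param window_end Date of the clinical encounter the profile looks back
#'   from; the window ends the day before it.
#' @param window_days Length of the look-back window in days (default 30).
#' @param min_days Minimum number of days with data (default 14).
#' @return One-row tibble: `patient_id`, `n_days_used`, `window_end`, and
#'   `hour_0` ... `hour_23` holding the mean smoothed steps per hour of day.
#' @export
build_mean_profile <- function(records, window_end, window_days = 30,
                               min_days = 14) {
  pid <- unique(records$patient_id)
  if (length(pid) != 1L) {
    stop("`records` must belong to exactly one patient", call. = FALSE)
  }
  window_end <- as.Date(window_end)
  days <- seq(window_end - window_days, by = "day", length.out = window_days)
  in_window <- records[records$date %in% days, ]

  n_days_used <- length(unique(in_window$date[!is.na(in_window$steps_sum)]))
  if (n_days_used < min_days) {
    stop(insufficient_data_error(pid, n_days_used, min_days))
  }

  grid <- tidyr::expand_grid(date = days, hour = 0:23) |>
    dplyr::left_join(
      in_window[, c("date", "hour", "steps_sum")],
      by = c("date", "hour")
    ) |>
    dplyr::arrange(.data$date, .data$hour)
  grid$smoothed <- smooth_hourly(grid$steps_sum)

  by_hour <- vapply(0:23, function(h) {
    v <- grid$smoothed[grid$hour == h]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))

  out <- tibble::tibble(patient_id = pid, n_days_used = n_days_used,
                        window_end = window_end)
  out[paste0("hour_", 0:23)] <- as.list(by_hour)
  out
}

#' Preprocess a whole cohort into activity profiles
#'
#' Runs the full preparation chain — missing-heart-rate nullification,
#' hourly aggregation, smoothing, hour-of-day averaging, and the
#' minimum-days sufficiency filter — for every patient in `series`, using
#' each patient's encounter date in `truth` as the end of the look-back
#' window.
#'
#' @param series Raw sample tibble (`patient_id`, `timestamp`, `steps`,
#'   `heart_rate`).
#' @param truth Metadata tibble with `patient_id` and `encounter_date`.
#' @param window_days,min_days See [build_mean_profile()].
#' @param null_granularity Where the missing-heart-rate rule nulls steps:
#'   `"hourly"` (null the hour when its median heart rate is missing, the
#'   default) or `"sample"` (null each raw sample first).
#' @param tz Time zone for the civil day/hour.
#' @return List with `profiles` (stacked profile rows of surviving patients)
#'   and `excluded` (tibble of `patient_id`, `n_days_used` for patients
#'   failing the sufficiency rule).
#' @export
preprocess_cohort <- function(series, truth, window_days = 30, min_days = 14,
                              null_granularity = c("hourly", "sample"),
                              tz = "UTC") {
  null_granularity <- match.arg(null_granularity)
  if (null_granularity == "sample") {
    series <- nullify_missing_hr(series)
  }
  hourly <- aggregate_hourly(series, tz = tz,
                             enforce_hr_rule = null_granularity == "hourly")
  profiles <- list()
  excluded <- list()
  for (pid in unique(hourly$patient_id)) {
    enc <- truth$encounter_date[truth$patient_id == pid]
    if (length(enc) != 1L) {
      stop(sprintf("patient '%s' has %d metadata rows; expected 1",
                   pid, length(enc)), call. = FALSE)
    }
    res <- tryCatch(
      build_mean_profile(hourly[hourly$patient_id == pid, ], enc,
                         window_days = window_days, min_days = min_days),
      watbarthel_insufficient_data = function(e) e
    )
    if (inherits(res, "condition")) {
      excluded[[pid]] <- tibble::tibble(patient_id = pid,
                                        n_days_used = res$n_days_used)
    } else {
      profiles[[pid]] <- res
    }
  }
  list(
    profiles = dplyr::bind_rows(profiles),
    excluded = if (length(excluded)) dplyr::bind_rows(excluded)
               else tibble::tibble(patient_id = character(),
                                   n_days_used = integer())
  )
}
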