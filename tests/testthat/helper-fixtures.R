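# Small builders used across the suite.

make_samples <- function(patient_id = "P1",
                         times,
                         steps,
                         heart_rate = rep(75, length(times))) {
  tibble::tibble(
    patient_id = patient_id,
    timestamp = as.POSIXct(times, tz = "UTC"),
    steps = as.integer(steps),
    heart_rate = heart_rate
  )
}

# n_days of per-hour samples (one sample per hour) with a fixed 24-value
# daily pattern of hourly step counts.
make_daily_pattern_samples <- function(pattern, n_days,
                                       start = as.Date("2022-01-01"),
                                       patient_id = "P1") {
  stopifnot(length(pattern) == 24L)
  times <- as.POSIXct(paste(rep(start + seq_len(n_days) - 1L, each = 24L),
                            sprintf("%02d:30:00", rep(0:23, n_days))),
                      tz = "UTC")
  make_samples(patient_id, times, rep(pattern, n_days))
}

# Random modeling table for tree tests: integer-ish features, BI-like target.
random_table <- function(n, p = 3, seed = NULL) {
  build <- function() {
    d <- tibble::tibble(.rows = n)
    for (j in seq_len(p)) {
      d[[paste0("f", j)]] <- round(stats::runif(n, 0, 100), 1)
    }
    d$barthel_index <- 5 * sample(0:20, n, replace = TRUE)
    d
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
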