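#' Simulation configuration for synthetic wearable-tracker cohorts
#'
#' Bundles and validates every knob of the synthetic actigraphy generator.
#' The defaults describe a cohort of elderly patients with complex chronic
#' disease wearing a wrist activity tracker: short activity bursts (at most
#' two consecutive hours) anchored to the Spanish meal timetable, per-patient
#' activity amplitude increasing with the true Barthel Index (BI),
#' walking-aid-dependent step undercounting by the wrist device, occasional
#' missing heart-rate samples, and a fraction of patients who stop wearing
#' the device early.
#'
#' @param n_patients Number of patients to simulate (0 gives an empty cohort).
#' @param days_recorded Days of continuous recording per patient.
#' @param seed Integer seed; the whole cohort is reproducible given the seed.
#' @param class_mix Proportions of dependence classes A/B/C (BI <= 20,
#'   20 < BI <= 60, BI > 60). Default mirrors a 90-patient cohort with
#'   10 A / 40 B / 40 C.
#' @param aid_mix_given_class 3 x 3 matrix of walking-aid proportions
#'   (rows A/B/C, columns none/cane_or_walker/wheelchair), each row summing
#'   to 1. Severely dependent patients are more likely to use a wheelchair.
#' @param burst_rate_by_class Mean number of activity bursts per day for
#'   classes A/B/C (Poisson rates).
#' @param burst_amplitude_by_class Mean true steps accumulated per burst-hour
#'   for classes A/B/C, before BI scaling and device attenuation.
#' @param meal_anchor_hours Hours of day (0-23) around which burst start
#'   times cluster; default 9 / 14 / 21 (breakfast, lunch, dinner in Spain).
#' @param anchor_sd Standard deviation, in hours, of burst start times
#'   around their meal anchor.
#' @param missing_hr_prob Probability that a sample's heart rate is missing.
#' @param dropout_prob Probability that a patient stops recording early, at a
#'   uniformly random point of the recording period.
#' @param aid_attenuation Multiplicative step-detection factors for
#'   none/cane_or_walker/wheelchair. Wrist devices undercount steps during
#'   assisted ambulation, most severely for wheelchair users.
#' @param sampling_interval_mins Sampling interval of the raw stream in
#'   minutes (default 1).
#' @param start_date First day of recording.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 5, days_recorded = 16, seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort$truth
sim_config <- function(n_patients,
                       days_recorded = 30,
                       seed = 1L,
                       class_mix = c(A = 1 / 9, B = 4 / 9, C = 4 / 9),
                       aid_mix_given_class = default_aid_mix(),
                       burst_rate_by_class = c(A = 2, B = 4, C = 6),
                       burst_amplitude_by_class = c(A = 60, B = 180, C = 400),
                       meal_anchor_hours = c(9, 14, 21),
                       anchor_sd = 1.25,
                       missing_hr_prob = 0.05,
                       dropout_prob = 0.1,
                       aid_attenuation = c(none = 1, cane_or_walker = 0.6,
                                           wheelchair = 0.15),
                       sampling_interval_mins = 1,
                       start_date = as.Date("2022-06-01")) {
  if (!is_count(n_patients, zero_ok = TRUE)) {
    stop("`n_patients` must be a nonnegative integer", call. = FALSE)
  }
  if (!is_count(days_recorded)) {
    stop("`days_recorded` must be a positive integer", call. = FALSE)
  }
  class_mix <- check_proportions(class_mix, "class_mix", BI_CLASS_LEVELS)
  aid_mix_given_class <- as.matrix(aid_mix_given_class)
  if (!all(dim(aid_mix_given_class) == c(3L, 3L))) {
    stop("`aid_mix_given_class` must be a 3 x 3 matrix (classes x aid groups)",
         call. = FALSE)
  }
  rownames(aid_mix_given_class) <- rownames(aid_mix_given_class) %||% BI_CLASS_LEVELS
  colnames(aid_mix_given_class) <- colnames(aid_mix_given_class) %||% AID_LEVELS
  for (cl in BI_CLASS_LEVELS) {
    check_proportions(aid_mix_given_class[cl, ],
                      sprintf("aid_mix_given_class['%s', ]", cl), AID_LEVELS)
  }
  stopifnot(
    "`burst_rate_by_class` must be 3 nonnegative rates" =
      length(burst_rate_by_class) == 3L && all(burst_rate_by_class >= 0),
    "`burst_amplitude_by_class` must be 3 nonnegative amplitudes" =
      length(burst_amplitude_by_class) == 3L && all(burst_amplitude_by_class >= 0),
    "`meal_anchor_hours` must lie in 0..23" =
      all(meal_anchor_hours >= 0 & meal_anchor_hours <= 23),
    "`anchor_sd` must be positive" = anchor_sd > 0,
    "`sampling_interval_mins` must divide an hour" =
      is_count(sampling_interval_mins) && 60 %% sampling_interval_mins == 0
  )
  if (!is_prob(missing_hr_prob)) {
    stop("`missing_hr_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (!is_prob(dropout_prob)) {
    stop("`dropout_prob` must lie in [0, 1]", call. = FALSE)
  }
  names(burst_rate_by_class) <- BI_CLASS_LEVELS
  names(burst_amplitude_by_class) <- BI_CLASS_LEVELS
  aid_attenuation <- aid_attenuation[AID_LEVELS]
  if (anyNA(aid_attenuation) || any(aid_attenuation < 0 | aid_attenuation > 1)) {
    stop("`aid_attenuation` must give factors in [0, 1] for none/cane_or_walker/wheelchair",
         call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      days_recorded = as.integer(days_recorded),
      seed = as.integer(seed),
      class_mix = class_mix,
      aid_mix_given_class = aid_mix_given_class,
      burst_rate_by_class = burst_rate_by_class,
      burst_amplitude_by_class = burst_amplitude_by_class,
      meal_anchor_hours = meal_anchor_hours,
      anchor_sd = anchor_sd,
      missing_hr_prob = missing_hr_prob,
      dropout_prob = dropout_prob,
      aid_attenuation = aid_attenuation,
      sampling_interval_mins = as.integer(sampling_interval_mins),
      start_date = as.Date(start_date)
    ),
    class = "sim_config"
  )
}

default_aid_mix <- function() {
  matrix(
    c(0.05, 0.25, 0.70,   # class A: mostly wheelchair-bound
      0.35, 0.45, 0.20,   # class B
      0.85, 0.13, 0.02),  # class C: mostly unaided
    nrow = 3, byrow = TRUE,
    dimnames = list(BI_CLASS_LEVELS, AID_LEVELS)
  )
}

# BI grids per dependence class: multiples of 5, as the instrument scores
bi_grid_for_class <- function(class) {
  switch(class,
         A = seq(0, 20, by = 5),
         B = seq(25, 60, by = 5),
         C = seq(65, 100, by = 5),
         stop("unknown class: ", class))
}

#' Generate a synthetic cohort of tracker streams with ground truth
#'
#' Draws, for each patient, a dependence class, a true Barthel Index on the
#' class-specific grid of multiples of 5, and a walking-aid group; then
#' simulates a per-minute step-count and heart-rate stream over
#' `days_recorded` days. Daily activity is a Poisson number of short bursts
#' whose start times cluster around meal anchors and which span at most two
#' consecutive hours. True steps per burst scale with the BI, so mean daily
#' steps increase with independence; recorded steps are then thinned
#' binomially by the walking-aid attenuation factor, reproducing wrist-device
#' undercounting for aided walkers and wheelchair users. Heart-rate samples
#' are set missing with `missing_hr_prob`, and with probability
#' `dropout_prob` a patient's stream stops at a uniformly random point.
#'
#' @param config A [sim_config()].
#' @return A list with components `truth` (tibble: `patient_id`, `true_bi`,
#'   `aid_group`, `bi_class`, `encounter_date`) and `series` (tibble:
#'   `patient_id`, `timestamp`, `steps`, `heart_rate`). `encounter_date` is
#'   the day after the scheduled end of recording, so the profile window
#'   looking back from it covers the recording.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  empty_truth <- tibble::tibble(
    patient_id = character(), true_bi = integer(),
    aid_group = character(), bi_class = character(),
    encounter_date = as.Date(character())
  )
  empty_series <- tibble::tibble(
    patient_id = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    steps = integer(), heart_rate = numeric()
  )
  if (config$n_patients == 0L) {
    return(list(truth = empty_truth, series = empty_series))
  }
  withr::with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%03d", seq_len(n))
    classes <- sample(BI_CLASS_LEVELS, n, replace = TRUE, prob = config$class_mix)
    true_bi <- vapply(classes, function(cl) {
      grid <- bi_grid_for_class(cl)
      grid[sample.int(length(grid), 1L)]
    }, numeric(1))
    aid <- vapply(classes, function(cl) {
      sample(AID_LEVELS, 1L, prob = config$aid_mix_given_class[cl, ])
    }, character(1))
    truth <- tibble::tibble(
      patient_id = ids,
      true_bi = as.integer(true_bi),
      aid_group = aid,
      bi_class = classes,
      encounter_date = config$start_date + config$days_recorded
    )
    series <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      simulate_patient_series(ids[i], classes[i], true_bi[i], aid[i], config)
    }))
    series <- inject_missingness(series, config)
    list(truth = truth, series = series)
  })
}

# One patient's raw stream. Uses the active RNG stream (seeded by the caller).
simulate_patient_series <- function(patient_id, class, true_bi, aid_group,
                                    config) {
  per_hour <- 60L %/% config$sampling_interval_mins
  n_samples <- config$days_recorded * 24L * per_hour
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  timestamp <- t0 + (seq_len(n_samples) - 1L) * config$sampling_interval_mins * 60
  steps <- integer(n_samples)

  rate <- config$burst_rate_by_class[[class]]
  # amplitude grows with independence: ~0.3x at BI 0 up to ~1.7x at BI 100
  amp <- config$burst_amplitude_by_class[[class]] * (0.3 + 1.4 * true_bi / 100)
  for (day in seq_len(config$days_recorded) - 1L) {
    n_bursts <- stats::rpois(1L, rate)
    if (n_bursts == 0L) next
    anchors <- sample(config$meal_anchor_hours, n_bursts, replace = TRUE)
    starts <- pmin(23L, pmax(0L, round(stats::rnorm(n_bursts, anchors,
                                                    config$anchor_sd))))
    # burst length geometric truncated at 2 h: 75% one hour, 25% two
    lens <- 1L + stats::rbinom(n_bursts, 1L, 0.25)
    for (b in seq_len(n_bursts)) {
      for (h in starts[b] + seq_len(lens[b]) - 1L) {
        if (h > 23L) next
        hour_offset <- (day * 24L + h) * per_hour
        active <- sample.int(per_hour, min(per_hour, sample(5:20, 1L) %/%
                                             config$sampling_interval_mins + 1L))
        burst_steps <- stats::rpois(length(active), amp / length(active))
        idx <- hour_offset + active
        steps[idx] <- steps[idx] + burst_steps
      }
    }
  }
  # the wrist device misses steps during assisted ambulation
  recorded <- stats::rbinom(n_samples, steps,
                            config$aid_attenuation[[aid_group]])
  hr_base <- stats::rnorm(1L, 72, 5)
  heart_rate <- round(hr_base + 12 * (recorded > 0) +
                        stats::rnorm(n_samples, 0, 3))

  out <- tibble::tibble(
    patient_id = patient_id,
    timestamp = timestamp,
    steps = as.integer(recorded),
    heart_rate = heart_rate
  )
  if (stats::runif(1L) < config$dropout_prob) {
    keep_until <- stats::runif(1L, 0, n_samples)
    out <- out[seq_len(max(1L, floor(keep_until))), ]
  }
  out
}

#' Blank out heart-rate samples at random
#'
#' Sets the heart rate of each sample to missing with probability
#' `missing_hr_prob`, leaving step counts and the sample count untouched.
#' Downstream preprocessing, not this function, decides how missing heart
#' rates nullify step counts.
#'
#' @param series Tibble with at least a `heart_rate` column.
#' @param config A [sim_config()], or a single probability in `[0, 1]`.
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return `series` with some `heart_rate` values set to `NA`.
#' @export
inject_missingness <- function(series, config, seed = NULL) {
  p <- if (inherits(config, "sim_config")) config$missing_hr_prob else config
  if (!is_prob(p)) stop("missing-probability must lie in [0, 1]", call. = FALSE)
  if (nrow(series) == 0L) stop("`series` must be non-empty", call. = FALSE)
  draw <- function() {
    series$heart_rate[stats::runif(nrow(series)) < p] <- NA_real_
    series
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
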