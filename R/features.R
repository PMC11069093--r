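#' Hour-of-day segmentation of the activity profile
#'
#' The 24-hour profile is partitioned into four segments aligned with the
#' Spanish daily routine: morning 07-13 h, afternoon 14-19 h, evening
#' 20-23 h, overnight 00-06 h. Each listed hour is an inclusive hourly bin
#' (so "13" covers 13:00-13:59), and the four segments are disjoint and
#' cover all 24 hours.
#'
#' @param morning,afternoon,evening,overnight Integer hour-of-day vectors.
#' @return Named list of hour vectors, class `segment_scheme`.
#' @export
segment_scheme <- function(morning = 7:13, afternoon = 14:19,
                           evening = 20:23, overnight = 0:6) {
  scheme <- list(morning = morning, afternoon = afternoon,
                 evening = evening, overnight = overnight)
  hours <- sort(unlist(scheme, use.names = FALSE))
  if (!identical(as.integer(hours), 0:23)) {
    stop("segments must be disjoint and cover hours 0..23 exactly",
         call. = FALSE)
  }
  structure(scheme, class = "segment_scheme")
}

#' Reduce a 24-hour profile to one value per segment
#'
#' Applies a reducer (maximum by default) to the profile values of each
#' segment. The maximum is the default because patient activity arrives in
#' short bursts, rarely longer than an hour, so the peak hourly step count
#' best represents a segment's activity level; `sum` and `mean` are provided
#' for comparison behind the same interface. Missing hours are skipped; a
#' segment with no observed hour reduces to 0 with a warning.
#'
#' @param values Numeric vector of length 24, hour 0 first (or a one-row
#'   profile tibble from [build_mean_profile()]).
#' @param scheme A [segment_scheme()].
#' @param reducer `"max"`, `"sum"`, or `"mean"`.
#' @return Named numeric vector `c(morning = , afternoon = , evening = ,
#'   overnight = )`.
#' @export
segment_maxima <- function(values, scheme = segment_scheme(),
                           reducer = c("max", "sum", "mean")) {
  reducer <- match.arg(reducer)
  if (is.data.frame(values)) {
    stopifnot(nrow(values) == 1L)
    values <- as.numeric(values[paste0("hour_", 0:23)])
  }
  stopifnot("profile must have exactly 24 hourly values" = length(values) == 24L)
  f <- switch(reducer, max = max, sum = sum, mean = mean)
  vapply(scheme, function(hours) {
    v <- values[hours + 1L]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      warning("segment has no observed hours; reducing to 0", call. = FALSE)
      return(0)
    }
    f(v)
  }, numeric(1))
}

#' One-hot encode the walking-aid group
#'
#' Patients are grouped by the walking aid they rely on, because wrist
#' trackers undercount steps during assisted ambulation: `"wheelchair"`,
#' `"cane_or_walker"` (canes, walkers, or a caregiver's help, which supports
#' walking the same way), or `"none"`. Caregiver-assisted walkers must be
#' coded `"cane_or_walker"` upstream.
#'
#' @param aid_group Character vector of group labels.
#' @return Tibble with 0/1 columns `no_walking_aid`, `cane_or_walker`,
#'   `wheelchair`; each row sums to 1.
#' @export
encode_aid_group <- function(aid_group) {
  bad <- setdiff(unique(aid_group), AID_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown walking-aid label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(AID_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    no_walking_aid = as.integer(aid_group == "none"),
    cane_or_walker = as.integer(aid_group == "cane_or_walker"),
    wheelchair = as.integer(aid_group == "wheelchair")
  )
}

#' Assemble the modeling table from profiles and patient metadata
#'
#' Joins each surviving activity profile with its patient's metadata and
#' produces one modeling row per patient: the four segment maxima, the
#' three walking-aid indicators, and the measured Barthel Index target.
#'
#' @param profiles Stacked profile rows from [preprocess_cohort()].
#' @param truth Metadata tibble with `patient_id`, `true_bi`, `aid_group`.
#' @param scheme A [segment_scheme()].
#' @param reducer Segment reducer passed to [segment_maxima()].
#' @param role Optional dataset role recorded on every row (for example
#'   `"test"` for production-like encounter-3 profiles, which
#'   [fit_tree()] refuses to train on).
#' @return Tibble with columns `patient_id`, `morning_max`, `afternoon_max`,
#'   `evening_max`, `overnight_max`, `no_walking_aid`, `cane_or_walker`,
#'   `wheelchair`, `aid_group`, `barthel_index` (and `role` if given).
#' @export
build_feature_table <- function(profiles, truth, scheme = segment_scheme(),
                                reducer = "max", role = NULL) {
  feature_cols <- c("morning_max", "afternoon_max", "evening_max",
                    "overnight_max")
  if (nrow(profiles) == 0L) {
    out <- tibble::tibble(patient_id = character())
    out[feature_cols] <- list(numeric())
    out$no_walking_aid <- integer()
    out$cane_or_walker <- integer()
    out$wheelchair <- integer()
    out$aid_group <- character()
    out$barthel_index <- numeric()
    return(out)
  }
  missing_ids <- setdiff(profiles$patient_id, truth$patient_id)
  if (length(missing_ids) > 0L) {
    stop("no metadata for patient(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  segs <- t(vapply(seq_len(nrow(profiles)), function(i) {
    segment_maxima(profiles[i, ], scheme = scheme, reducer = reducer)
  }, numeric(4)))
  meta <- truth[match(profiles$patient_id, truth$patient_id), ]
  out <- tibble::tibble(patient_id = profiles$patient_id)
  out[feature_cols] <- as.data.frame(segs)
  out <- dplyr::bind_cols(out, encode_aid_group(meta$aid_group))
  out$aid_group <- meta$aid_group
  out$barthel_index <- as.numeric(meta$true_bi)
  if (!is.null(role)) out$role <- role
  out
}
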