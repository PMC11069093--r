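# CSV dialect used throughout: comma-separated, UTF-8, ISO-8601 timestamps,
# empty field = missing.

check_columns <- function(df, required, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
}

#' Read and write wearable-tracker sample streams
#'
#' Long-format CSV with columns `patient_id`, `timestamp` (ISO-8601),
#' `steps`, `heart_rate`; an empty field is a missing value. The same schema
#' accepts real tracker exports and the synthetic generator's output.
#'
#' @param path CSV file path.
#' @param tz Time zone in which timestamps are read.
#' @return `read_wat_csv()`: tibble of samples.
#' @export
read_wat_csv <- function(path, tz = "UTC") {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    timestamp = readr::col_datetime(),
    steps = readr::col_double(),
    heart_rate = readr::col_double()
  ), locale = readr::locale(tz = tz), progress = FALSE)
  check_columns(df, c("patient_id", "timestamp", "steps", "heart_rate"), path)
  bad <- which(!is.na(df$steps) & df$steps < 0)
  if (length(bad) > 0L) {
    stop(sprintf("'%s': negative step count in column 'steps' at row %d",
                 path, bad[1L]), call. = FALSE)
  }
  df
}

#' @rdname read_wat_csv
#' @param series Sample tibble to write.
#' @export
write_wat_csv <- function(series, path) {
  out <- series
  out$timestamp <- format(series$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read and write patient metadata
#'
#' CSV with columns `patient_id`, `true_bi` (0-100), `aid_group`
#' (none / cane_or_walker / wheelchair), `encounter_date` (ISO date).
#'
#' @param path CSV file path.
#' @return `read_metadata_csv()`: tibble of patient metadata.
#' @export
read_metadata_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    true_bi = readr::col_double(),
    aid_group = readr::col_character(),
    encounter_date = readr::col_date()
  ), progress = FALSE)
  check_columns(df, c("patient_id", "true_bi", "aid_group", "encounter_date"),
                path)
  bad <- which(is.na(df$true_bi) | df$true_bi < 0 | df$true_bi > 100)
  if (length(bad) > 0L) {
    stop(sprintf("'%s': column 'true_bi' out of [0, 100] at row %d",
                 path, bad[1L]), call. = FALSE)
  }
  bad <- which(!df$aid_group %in% AID_LEVELS)
  if (length(bad) > 0L) {
    stop(sprintf("'%s': column 'aid_group' has unknown label '%s' at row %d",
                 path, df$aid_group[bad[1L]], bad[1L]), call. = FALSE)
  }
  df
}

#' @rdname read_metadata_csv
#' @param truth Metadata tibble to write.
#' @export
write_metadata_csv <- function(truth, path) {
  readr::write_csv(truth, path, na = "")
  invisible(path)
}

#' Write activity profiles or the modeling table as CSV
#'
#' Profiles are written wide (`patient_id`, `hour_0` ... `hour_23`,
#' `n_days_used`); the modeling table keeps its feature-schema column names
#' (`morning_max`, ..., `wheelchair`, `barthel_index`).
#'
#' @param profiles Stacked profile rows.
#' @param path CSV file path.
#' @export
write_profiles_csv <- function(profiles, path) {
  cols <- c("patient_id", paste0("hour_", 0:23), "n_days_used")
  readr::write_csv(profiles[, cols], path, na = "")
  invisible(path)
}

#' @rdname write_profiles_csv
#' @param features Modeling table from [build_feature_table()].
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path, na = "")
  invisible(path)
}
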