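`%||%` <- function(x, y) if (is.null(x)) y else x

AID_LEVELS <- c("none", "cane_or_walker", "wheelchair")
BI_CLASS_LEVELS <- c("A", "B", "C")

is_count <- function(x, zero_ok = FALSE) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) &&
    (x > 0 || (zero_ok && x == 0))
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

check_proportions <- function(x, name, levels) {
  if (!is.numeric(x) || length(x) != length(levels)) {
    stop(sprintf("`%s` must be a numeric vector of length %d (%s)",
                 name, length(levels), paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(names(x))) names(x) <- levels
  x <- x[levels]
  if (anyNA(x) || any(x < 0)) {
    stop(sprintf("`%s` must be nonnegative and named by %s",
                 name, paste(levels, collapse = "/")), call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop(sprintf("`%s` must sum to 1 (got %.12f)", name, sum(x)), call. = FALSE)
  }
  x
}

# named condition so callers can distinguish exclusion from real failures
insufficient_data_error <- function(patient_id, n_days_used, min_days) {
  structure(
    class = c("watbarthel_insufficient_data", "error", "condition"),
    list(
      message = sprintf(
        "patient '%s' has %d day(s) with data in the window; %d required",
        patient_id, n_days_used, min_days),
      call = NULL,
      patient_id = patient_id,
      n_days_used = n_days_used
    )
  )
}
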