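# Independent brute-force oracles. These recompute the same quantities as
# the package by direct enumeration, sharing no code with the implementation.

# Exhaustive greedy CART: at each node try every feature and every midpoint
# between consecutive distinct values, computing child SSEs by direct
# subsetting. Ties (within tol) resolve to the lowest feature index, then
# the lowest threshold.
oracle_cart <- function(data, target = "barthel_index",
                        features = setdiff(names(data), target),
                        min_impurity_decrease = 0, min_samples_leaf = 1,
                        min_samples_split = 2, max_depth = Inf, tol = 1e-9) {
  X <- as.matrix(data[, features, drop = FALSE])
  y <- as.numeric(data[[target]])
  n_total <- length(y)
  sse <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  grow <- function(rows, depth) {
    yn <- y[rows]
    node <- list(n = length(rows), value = mean(yn))
    if (length(rows) < min_samples_split || depth >= max_depth ||
        sse(yn) <= 0) {
      return(node)
    }
    best <- NULL
    for (j in seq_along(features)) {
      vals <- sort(unique(X[rows, j]))
      if (length(vals) < 2) next
      for (i in seq_len(length(vals) - 1)) {
        thr <- (vals[i] + vals[i + 1]) / 2
        left <- rows[X[rows, j] <= thr]
        right <- rows[X[rows, j] > thr]
        if (length(left) < min_samples_leaf ||
            length(right) < min_samples_leaf) next
        q <- sse(y[left]) + sse(y[right])
        if (is.null(best) || q < best$q - tol) {
          best <- list(j = j, thr = thr, q = q, left = left, right = right)
        }
      }
    }
    if (is.null(best)) return(node)
    decrease <- (sse(yn) - best$q) / n_total
    if (decrease < min_impurity_decrease) return(node)
    node$feature <- features[best$j]
    node$threshold <- best$thr
    node$left <- grow(best$left, depth + 1)
    node$right <- grow(best$right, depth + 1)
    node
  }
  grow(seq_len(n_total), 0)
}

oracle_cart_predict <- function(node, newdata) {
  one <- function(nd, row) {
    while (!is.null(nd$feature)) {
      nd <- if (newdata[[nd$feature]][row] <= nd$threshold) nd$left else nd$right
    }
    nd$value
  }
  vapply(seq_len(nrow(newdata)), function(r) one(node, r), numeric(1))
}

# Compare a fitted bi_tree with an oracle tree: same shape, same split
# features/thresholds, same leaf sizes and values.
expect_same_tree <- function(fit, oracle) {
  walk <- function(a, b, path) {
    a_leaf <- is.null(a$feature_index)
    b_leaf <- is.null(b$feature)
    expect(a_leaf == b_leaf,
           sprintf("node %s: leaf status differs (fit %s, oracle %s)",
                   path, a_leaf, b_leaf))
    if (a_leaf || b_leaf) {
      if (a_leaf && b_leaf) {
        expect_equal(a$n, b$n, info = paste("leaf n at", path))
        expect_equal(a$value, b$value, info = paste("leaf value at", path))
      }
      return(invisible())
    }
    expect_equal(fit$feature_names[a$feature_index], b$feature,
                 info = paste("split feature at", path))
    expect_equal(a$threshold, b$threshold,
                 info = paste("threshold at", path))
    walk(a$left, b$left, paste0(path, "L"))
    walk(a$right, b$right, paste0(path, "R"))
  }
  walk(fit$root, oracle, "root")
}

# Brute-force mean activity profile: hourly nulling, day/hour aggregation,
# flat-series smoothing and hour-of-day averaging, all as explicit loops.
oracle_profile <- function(samples, window_end, window_days = 30,
                           min_days = 14) {
  window_end <- as.Date(window_end)
  days <- seq(window_end - window_days, by = "day", length.out = window_days)
  lt <- as.POSIXlt(samples$timestamp, tz = "UTC")
  s_date <- as.Date(format(lt, "%Y-%m-%d"))
  s_hour <- lt$hour
  steps_mat <- matrix(NA_real_, window_days, 24)
  for (d in seq_along(days)) {
    for (h in 0:23) {
      sel <- s_date == days[d] & s_hour == h
      if (!any(sel)) next
      hr <- samples$heart_rate[sel]
      st <- samples$steps[sel]
      med <- if (all(is.na(hr))) NA_real_ else stats::median(hr, na.rm = TRUE)
      total <- if (all(is.na(st))) NA_real_ else sum(st, na.rm = TRUE)
      if (is.na(med)) total <- NA_real_  # hourly null rule
      steps_mat[d, h + 1] <- total
    }
  }
  n_days_used <- sum(apply(steps_mat, 1, function(r) any(!is.na(r))))
  if (n_days_used < min_days) return(NULL)
  flat <- as.vector(t(steps_mat))  # chronological: day 1 h0..h23, day 2 ...
  sm <- rep(NA_real_, length(flat))
  for (i in seq_along(flat)) {
    if (is.na(flat[i])) next
    neigh <- flat[max(1, i - 1):min(length(flat), i + 1)]
    sm[i] <- mean(neigh, na.rm = TRUE)
  }
  sm_mat <- matrix(sm, window_days, 24, byrow = TRUE)
  prof <- numeric(24)
  for (h in 1:24) {
    v <- sm_mat[, h]
    prof[h] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  list(values = prof, n_days_used = n_days_used)
}
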