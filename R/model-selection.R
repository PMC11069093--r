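#' Stratified train/validation split by walking-aid group
#'
#' Splits the modeling table so that each walking-aid group contributes
#' `train_fraction` of its rows to the training set, keeping the groups'
#' proportions equal in both sets. Within each group rows are shuffled
#' (seeded) and allocated by largest-remainder rounding, so the training
#' total equals `round(train_fraction * N)` exactly — for example 90 rows at
#' 0.7 give 63 train and 27 validation. A group with fewer than 2 rows
#' cannot be split and goes entirely to training, with a warning.
#'
#' @param data Modeling tibble.
#' @param train_fraction Fraction allocated to training, strictly in (0, 1).
#' @param group_col Name of the stratification column (default
#'   `"aid_group"`).
#' @param seed Integer seed controlling the within-group shuffles.
#' @return List with tibbles `train` and `validation`; together they
#'   partition `data`.
#' @export
stratified_split <- function(data, train_fraction = 0.7,
                             group_col = "aid_group", seed = 1L) {
  stopifnot(
    "`train_fraction` must lie strictly between 0 and 1" =
      train_fraction > 0 && train_fraction < 1,
    "`data` must contain the stratification column" = group_col %in% names(data)
  )
  groups <- data[[group_col]]
  if (anyNA(groups)) stop("every row needs a walking-aid group", call. = FALSE)
  withr::with_seed(seed, {
    sizes <- table(groups)
    small <- names(sizes)[sizes < 2L]
    if (length(small) > 0L) {
      warning("group(s) with fewer than 2 rows go entirely to training: ",
              paste(small, collapse = ", "), call. = FALSE)
    }
    eligible <- setdiff(names(sizes), small)
    n_eligible <- sum(sizes[eligible])
    quota <- train_fraction * as.numeric(sizes[eligible])
    base <- floor(quota)
    extra <- round(train_fraction * n_eligible) - sum(base)
    take <- base
    if (extra > 0L) {
      # largest fractional remainders get the leftover seats
      ord <- order(-(quota - base), seq_along(quota))
      take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
    }
    names(take) <- eligible
    train_idx <- integer()
    for (g in names(sizes)) {
      rows <- which(groups == g)
      rows <- rows[sample.int(length(rows))]
      n_train <- if (g %in% small) length(rows) else take[[g]]
      train_idx <- c(train_idx, rows[seq_len(n_train)])
    }
    train_idx <- sort(train_idx)
    list(train = data[train_idx, ], validation = data[-train_idx, ])
  })
}

#' The default cross-validation hyperparameter grid
#'
#' `min_impurity_decrease` from 0 to 1 in steps of 0.01,
#' `min_samples_leaf` 1 to 10, and `min_samples_split` 1 to 10 —
#' 101 x 10 x 10 = 10,100 candidates.
#'
#' @return Data frame with one row per candidate.
#' @export
default_cv_grid <- function() {
  expand.grid(
    min_impurity_decrease = seq(0, 1, by = 0.01),
    min_samples_leaf = 1:10,
    min_samples_split = 1:10,
    KEEP.OUT.ATTRS = FALSE
  )
}

# Held-out predictions of the pruned tree for every min_impurity_decrease
# value at once. A tree constrained by min_impurity_decrease = m equals the
# unconstrained tree pruned at nodes whose best-split decrease falls below
# m, because the split choice itself never depends on m; this turns the
# 101-value sweep into a single fit per (min_samples_leaf,
# min_samples_split) candidate.
predict_pruned_sweep <- function(root, X, mids) {
  out <- matrix(NA_real_, nrow(X), length(mids))
  route <- function(node, rows, cols) {
    if (length(rows) == 0L || length(cols) == 0L) return(invisible())
    if (is.null(node$feature_index)) {
      out[rows, cols] <<- node$value
      return(invisible())
    }
    pruned <- cols[mids[cols] > node$decrease]
    if (length(pruned) > 0L) out[rows, pruned] <<- node$value
    keep <- setdiff(cols, pruned)
    if (length(keep) == 0L) return(invisible())
    go_left <- X[rows, node$feature_index] <= node$threshold
    route(node$left, rows[go_left], keep)
    route(node$right, rows[!go_left], keep)
  }
  route(root, seq_len(nrow(X)), seq_along(mids))
  out
}

#' Grid-search hyperparameters by k-fold cross-validation
#'
#' Evaluates every candidate of the hyperparameter grid by its mean
#' held-out score over `k` shuffled folds and returns the best candidate.
#' The default score is negative mean squared error; negative median
#' absolute error is available as a robust alternative, step counts from
#' wrist devices being noisy. Ties are broken toward the lexicographically
#' smallest (`min_impurity_decrease`, `min_samples_leaf`,
#' `min_samples_split`) tuple, making the selection deterministic.
#'
#' @param data Training tibble.
#' @param grid Data frame of candidates; defaults to [default_cv_grid()].
#' @param k Number of folds (default 7).
#' @param scoring `"neg_mse"` or `"neg_mad"`.
#' @param seed Seed for the fold shuffle.
#' @param target,features Passed to [fit_tree()].
#' @param max_depth Optional depth cap applied to every candidate.
#' @return List with `best` (a [hyperparams()]), `scores` (tibble: grid plus
#'   `mean_score`), `k`, `scoring`.
#' @export
cross_validate <- function(data, grid = default_cv_grid(), k = 7,
                           scoring = c("neg_mse", "neg_mad"), seed = 1L,
                           target = "barthel_index", features = NULL,
                           max_depth = Inf) {
  scoring <- match.arg(scoring)
  n <- nrow(data)
  if (k > n) stop(sprintf("k = %d folds but only %d rows", k, n), call. = FALSE)
  stopifnot(k >= 2)
  grid <- as.data.frame(grid)
  needed <- c("min_impurity_decrease", "min_samples_leaf", "min_samples_split")
  stopifnot(all(needed %in% names(grid)))
  if (any(grid$min_samples_split < 2L)) {
    warning("min_samples_split = 1 cannot produce a binary split; ",
            "treating it as 2", call. = FALSE)
  }

  features <- features %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))],
            c(target, "patient_id", "aid_group", "role", "n_days_used"))
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.numeric(data[[target]])

  fold_of <- withr::with_seed(seed, {
    idx <- sample.int(n)
    f <- integer(n)
    f[idx] <- rep_len(seq_len(k), n)
    f
  })
  score_fun <- switch(scoring,
    neg_mse = function(truth, pred) -mean((truth - pred)^2),
    neg_mad = function(truth, pred) -stats::median(abs(truth - pred))
  )

  # one full fit per fold x (min_samples_leaf, min_samples_split) candidate;
  # the min_impurity_decrease axis is evaluated by pruning that fit
  combos <- unique(grid[, c("min_samples_leaf", "min_samples_split")])
  total_score <- numeric(nrow(grid))
  for (f in seq_len(k)) {
    hold <- fold_of == f
    train_data <- data[!hold, , drop = FALSE]
    for (ci in seq_len(nrow(combos))) {
      msl <- combos$min_samples_leaf[ci]
      mss <- max(2L, combos$min_samples_split[ci])
      hp <- suppressWarnings(
        hyperparams(0, msl, mss, max_depth = max_depth))
      fit <- fit_tree(train_data, hp, target = target, features = features)
      rows <- which(
        grid$min_samples_leaf == combos$min_samples_leaf[ci] &
          grid$min_samples_split == combos$min_samples_split[ci])
      mids <- grid$min_impurity_decrease[rows]
      preds <- predict_pruned_sweep(fit$root, X[hold, , drop = FALSE], mids)
      for (m in seq_along(rows)) {
        total_score[rows[m]] <- total_score[rows[m]] +
          score_fun(y[hold], preds[, m])
      }
    }
  }
  scores <- tibble::as_tibble(grid)
  scores$mean_score <- total_score / k

  best_score <- max(scores$mean_score)
  cand <- which(scores$mean_score >= best_score - 1e-12)
  cand <- cand[order(scores$min_impurity_decrease[cand],
                     scores$min_samples_leaf[cand],
                     scores$min_samples_split[cand])]
  best_row <- scores[cand[1L], ]
  best <- suppressWarnings(hyperparams(
    best_row$min_impurity_decrease,
    best_row$min_samples_leaf,
    max(2L, best_row$min_samples_split),
    max_depth = max_depth
  ))
  list(best = best, scores = scores, k = k, scoring = scoring, seed = seed)
}

#' Permutation importance of each feature
#'
#' Shuffles one feature column at a time (`n_repeats` independent shuffles)
#' and records the decrease in the model's R-squared on the supplied table.
#' The full distribution of decreases is returned (suitable for violin-style
#' summaries) together with per-feature means, sorted by decreasing
#' importance. A feature the tree never splits on gets importance 0 up to
#' sampling noise.
#'
#' @param model A fitted `bi_tree`.
#' @param data Tibble with the features and the target column.
#' @param n_repeats Shuffles per feature (default 50).
#' @param seed Seed making the shuffles reproducible.
#' @param target Target column name.
#' @return List with `baseline_r2`, `samples` (tibble: `feature`, `repeat_id`,
#'   `importance`), and `summary` (tibble: `feature`, `mean_importance`,
#'   descending).
#' @export
permutation_importance <- function(model, data, n_repeats = 50, seed = 1L,
                                   target = "barthel_index") {
  stopifnot(inherits(model, "bi_tree"))
  y <- as.numeric(data[[target]])
  baseline <- r_squared(y, predict(model, data))
  samples <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(model$feature_names, function(f) {
      imp <- vapply(seq_len(n_repeats), function(r) {
        shuffled <- data
        shuffled[[f]] <- sample(shuffled[[f]])
        baseline - r_squared(y, predict(model, shuffled))
      }, numeric(1))
      tibble::tibble(feature = f, repeat_id = seq_len(n_repeats),
                     importance = imp)
    }))
  })
  summary <- samples |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_importance = mean(.data$importance),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_importance))
  list(baseline_r2 = baseline, samples = samples, summary = summary)
}
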