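#' Hyperparameters of the regression tree
#'
#' @param min_impurity_decrease Minimum weighted impurity decrease
#'   (reduction in node MSE scaled by the node's fraction of the training
#'   set) required to accept a split. In BI-squared units.
#' @param min_samples_leaf Minimum number of training rows in each child.
#' @param min_samples_split Minimum rows a node needs to be considered for
#'   splitting. A binary split needs at least 2 rows, so a value of 1 is
#'   clamped to 2 with a warning.
#' @param max_depth Optional depth cap (root has depth 0); unlimited by
#'   default — tree depth is normally controlled by the other parameters.
#' @return List of class `bi_hyperparams`.
#' @export
hyperparams <- function(min_impurity_decrease = 0, min_samples_leaf = 1L,
                        min_samples_split = 2L, max_depth = Inf) {
  stopifnot(
    "`min_impurity_decrease` must be a nonnegative number" =
      length(min_impurity_decrease) == 1L && min_impurity_decrease >= 0,
    "`min_samples_leaf` must be a positive integer" =
      is_count(min_samples_leaf),
    "`min_samples_split` must be a positive integer" =
      is_count(min_samples_split),
    "`max_depth` must be positive or Inf" =
      (is.infinite(max_depth) && max_depth > 0) || is_count(max_depth)
  )
  if (min_samples_split < 2L) {
    warning("min_samples_split = 1 cannot produce a binary split; clamping to 2",
            call. = FALSE)
    min_samples_split <- 2L
  }
  structure(
    list(min_impurity_decrease = as.numeric(min_impurity_decrease),
         min_samples_leaf = as.integer(min_samples_leaf),
         min_samples_split = as.integer(min_samples_split),
         max_depth = max_depth),
    class = "bi_hyperparams"
  )
}

# Tolerance for comparing split qualities: ties within this are broken in
# favour of the earlier (lower feature index, lower threshold) candidate.
SPLIT_TIE_TOL <- 1e-9

# Best split of one node. X: numeric matrix (rows of this node), y: targets.
# Returns NULL or list(j, threshold, sse_children, n_left).
find_best_split <- function(X, y, min_samples_leaf) {
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j], method = "radix")
    xs <- X[o, j]
    ys <- y[o]
    cuts <- which(xs[-n] < xs[-1])  # split between positions i and i+1
    cuts <- cuts[cuts >= min_samples_leaf & (n - cuts) >= min_samples_leaf]
    if (length(cuts) == 0L) next
    cs <- cumsum(ys)
    css <- cumsum(ys * ys)
    nl <- cuts
    nr <- n - cuts
    sl <- cs[cuts]
    sr <- cs[n] - sl
    sse_l <- css[cuts] - sl * sl / nl
    sse_r <- (css[n] - css[cuts]) - sr * sr / nr
    sse_children <- sse_l + sse_r
    # ties within tolerance: lowest threshold wins
    i_best <- which(sse_children <= min(sse_children) + SPLIT_TIE_TOL)[1L]
    if (is.null(best) ||
        sse_children[i_best] < best$sse_children - SPLIT_TIE_TOL) {
      cut <- cuts[i_best]
      best <- list(j = j,
                   threshold = (xs[cut] + xs[cut + 1L]) / 2,
                   sse_children = sse_children[i_best],
                   n_left = cut)
    }
  }
  best
}

# Grows the full tree (no impurity-decrease gate), recording at every
# internal node the weighted decrease its split achieves. fit_tree() and the
# cross-validation both obtain constrained trees by pruning this one: the
# split chosen at a node does not depend on min_impurity_decrease, which
# only decides whether the best split is accepted.
grow_tree <- function(X, y, idx, depth, hp, n_total) {
  y_node <- y[idx]
  n <- length(idx)
  v <- mean(y_node)
  sse <- sum((y_node - v)^2)
  node <- list(n = n, value = v, squared_error = sse / n)
  if (n < hp$min_samples_split || depth >= hp$max_depth || sse <= 0) {
    return(node)
  }
  bs <- find_best_split(X[idx, , drop = FALSE], y_node, hp$min_samples_leaf)
  if (is.null(bs)) return(node)
  node$feature_index <- bs$j
  node$threshold <- bs$threshold
  node$decrease <- (sse - bs$sse_children) / n_total
  go_left <- X[idx, bs$j] <= bs$threshold
  node$left <- grow_tree(X, y, idx[go_left], depth + 1L, hp, n_total)
  node$right <- grow_tree(X, y, idx[!go_left], depth + 1L, hp, n_total)
  node
}

prune_tree <- function(node, min_impurity_decrease) {
  if (is.null(node$feature_index) || node$decrease < min_impurity_decrease) {
    return(list(n = node$n, value = node$value,
                squared_error = node$squared_error))
  }
  node$left <- prune_tree(node$left, min_impurity_decrease)
  node$right <- prune_tree(node$right, min_impurity_decrease)
  node
}

#' Fit a variance-reduction regression tree
#'
#' Greedy binary recursive partitioning of the feature space minimising the
#' weighted within-node sum of squared errors of the Barthel Index target —
#' the classic regression-tree (CART) criterion. Candidate thresholds are
#' midpoints between consecutive distinct values of each feature; a split is
#' accepted only if its weighted impurity decrease reaches
#' `min_impurity_decrease` and both children hold at least
#' `min_samples_leaf` rows. Leaves predict the mean target of their training
#' rows. Ties in split quality are broken toward the lowest feature index,
#' then the lowest threshold, so fits are fully deterministic.
#'
#' @param data Modeling tibble (for example from [build_feature_table()]).
#'   Rows tagged `role == "test"` are refused: production-like test profiles
#'   must never enter training.
#' @param hp A [hyperparams()] object.
#' @param target Name of the target column.
#' @param features Feature column names; by default every numeric column
#'   except the target and the bookkeeping columns
#'   (`patient_id`, `aid_group`, `role`).
#' @return Object of class `bi_tree`.
#' @export
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 3, 10, 11, 12),
#'                     y = c(0, 0, 0, 100, 100, 100))
#' fit <- fit_tree(d, target = "y")
#' predict(fit, tibble::tibble(x = c(2, 11)))
fit_tree <- function(data, hp = hyperparams(), target = "barthel_index",
                     features = NULL) {
  if (nrow(data) == 0L) stop("cannot fit a tree on an empty table", call. = FALSE)
  if ("role" %in% names(data) && any(data$role == "test")) {
    stop("`data` contains rows tagged role = \"test\"; ",
         "held-out test profiles must not be used for training", call. = FALSE)
  }
  stopifnot(inherits(hp, "bi_hyperparams"))
  features <- features %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))],
            c(target, "patient_id", "aid_group", "role", "n_days_used"))
  if (!target %in% names(data)) {
    stop(sprintf("target column '%s' not found", target), call. = FALSE)
  }
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.numeric(data[[target]])
  if (!all(is.finite(y))) stop("targets must be finite", call. = FALSE)
  root <- grow_tree(X, y, seq_along(y), 0L, hp, n_total = length(y))
  root <- prune_tree(root, hp$min_impurity_decrease)
  structure(
    list(root = root, feature_names = features, target = target,
         target_range = range(y), n_train = length(y), hp = hp),
    class = "bi_tree"
  )
}

#' Predict Barthel Index values from a fitted tree
#'
#' Routes each row down the tree (feature value `<=` threshold goes left)
#' and returns the training-mean of the leaf reached; predictions therefore
#' always lie within the range of the training targets.
#'
#' @param object A `bi_tree`.
#' @param newdata Tibble containing every training feature column.
#' @param ... Unused.
#' @return Numeric vector of predicted BI values.
#' @export
predict.bi_tree <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0L) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  out <- numeric(nrow(X))
  route <- function(node, rows) {
    if (length(rows) == 0L) return(invisible())
    if (is.null(node$feature_index)) {
      out[rows] <<- node$value
      return(invisible())
    }
    go_left <- X[rows, node$feature_index] <= node$threshold
    route(node$left, rows[go_left])
    route(node$right, rows[!go_left])
  }
  route(object$root, seq_len(nrow(X)))
  out
}

tree_depth <- function(node) {
  if (is.null(node$feature_index)) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_n_leaves <- function(node) {
  if (is.null(node$feature_index)) return(1L)
  tree_n_leaves(node$left) + tree_n_leaves(node$right)
}

#' @export
print.bi_tree <- function(x, digits = 2, ...) {
  cat(sprintf("Regression tree for '%s': %d training rows, depth %d, %d leaves\n",
              x$target, x$n_train, tree_depth(x$root), tree_n_leaves(x$root)))
  render <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$feature_index)) {
      cat(sprintf("%s* value = %s (n = %d, squared_error = %s)\n", pad,
                  format(round(node$value, digits)), node$n,
                  format(round(node$squared_error, digits))))
    } else {
      fname <- x$feature_names[node$feature_index]
      cat(sprintf("%s%s <= %s (n = %d, squared_error = %s)\n", pad, fname,
                  format(round(node$threshold, digits)), node$n,
                  format(round(node$squared_error, digits))))
      render(node$left, indent + 1L)
      pad2 <- strrep("  ", indent)
      cat(sprintf("%s%s >  %s\n", pad2, fname,
                  format(round(node$threshold, digits))))
      render(node$right, indent + 1L)
    }
  }
  render(x$root, 0L)
  invisible(x)
}

#' Serialize a fitted tree to JSON (and back)
#'
#' Nested node records carry the split feature, threshold, node size, node
#' mean squared error, and leaf value — everything needed to redraw the
#' fitted tree or reload it for prediction.
#'
#' @param model A `bi_tree`.
#' @param path File to write; if `NULL`, the JSON string is returned.
#' @export
write_model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "bi_tree"))
  node_to_list <- function(node) {
    base <- list(n = node$n, value = node$value,
                 squared_error = node$squared_error)
    if (is.null(node$feature_index)) return(c(base, list(leaf = TRUE)))
    c(base, list(
      leaf = FALSE,
      feature = model$feature_names[node$feature_index],
      threshold = node$threshold,
      left = node_to_list(node$left),
      right = node_to_list(node$right)
    ))
  }
  payload <- list(
    feature_names = model$feature_names,
    target = model$target,
    target_range = model$target_range,
    n_train = model$n_train,
    hyperparams = unclass(model$hp)[c("min_impurity_decrease",
                                      "min_samples_leaf",
                                      "min_samples_split")],
    root = node_to_list(model$root)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model_json
#' @param json_path Path of a JSON file written by [write_model_json()].
#' @export
read_model_json <- function(json_path) {
  payload <- jsonlite::fromJSON(json_path, simplifyVector = FALSE)
  feature_names <- unlist(payload$feature_names)
  list_to_node <- function(lst) {
    node <- list(n = lst$n, value = lst$value,
                 squared_error = lst$squared_error)
    if (isTRUE(lst$leaf)) return(node)
    node$feature_index <- match(lst$feature, feature_names)
    node$threshold <- lst$threshold
    node$left <- list_to_node(lst$left)
    node$right <- list_to_node(lst$right)
    node
  }
  hp <- payload$hyperparams
  structure(
    list(root = list_to_node(payload$root),
         feature_names = feature_names,
         target = payload$target,
         target_range = unlist(payload$target_range),
         n_train = payload$n_train,
         hp = hyperparams(hp$min_impurity_decrease, hp$min_samples_leaf,
                          hp$min_samples_split)),
    class = "bi_tree"
  )
}
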