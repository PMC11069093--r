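r_squared <- function(truth, pred) {
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    return(if (ss_res == 0) 1 else -Inf)
  }
  1 - ss_res / ss_tot
}

#' Regression error metrics for Barthel Index predictions
#'
#' Mean absolute error, median absolute error (MAD), root mean squared
#' error, and R-squared. The MAD is the preferred headline metric for this
#' problem: wrist-tracker step counts are noisy and a single badly measured
#' patient can dominate mean- or squared-error summaries.
#'
#' @param truth,pred Numeric vectors of equal, nonzero length (BI points).
#' @return Named list `mae`, `mad`, `rmse`, `r2`.
#' @export
#' @examples
#' regression_metrics(c(1, -2, 3), c(0, 0, 0)) # mae 2, mad 2, rmse sqrt(14/3)
regression_metrics <- function(truth, pred) {
  if (length(truth) == 0L || length(truth) != length(pred)) {
    stop("`truth` and `pred` must have equal nonzero length", call. = FALSE)
  }
  e <- truth - pred
  list(
    mae = mean(abs(e)),
    mad = stats::median(abs(e)),
    rmse = sqrt(mean(e^2)),
    r2 = r_squared(truth, pred)
  )
}

#' Convert a Barthel Index value to its dependence class
#'
#' Class A is total dependence (BI <= 20), class B severe dependence
#' (20 < BI <= 60), and class C moderate or mild dependence, or independence
#' (BI > 60). The same cutoffs are applied to measured and to predicted —
#' possibly non-integer — BI values.
#'
#' @param bi Numeric vector of finite BI values.
#' @return Factor with levels `A`, `B`, `C`.
#' @export
#' @examples
#' bi_to_class(c(20, 60, 60.4)) # A B C
bi_to_class <- function(bi) {
  if (!all(is.finite(bi))) stop("BI values must be finite", call. = FALSE)
  cut(bi, breaks = c(-Inf, 20, 60, Inf), labels = BI_CLASS_LEVELS)
}

#' F1 score from a precision/recall pair
#'
#' Harmonic mean of precision and recall; defined as 0 when both are 0.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return Numeric vector of F1 scores.
#' @export
f1_from_pr <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Multiclass classification report for dependence classes
#'
#' Confusion matrix (true classes in rows, predicted in columns), per-class
#' precision, recall, and F1, and overall accuracy for the A/B/C dependence
#' labels. A class that is never predicted (or has no support) gets 0.00 for
#' the undefined metric, with a warning — a class with a single instance can
#' legitimately score 0 across the board.
#'
#' @param truth,pred Vectors of labels in `{A, B, C}`.
#' @return List of class `class_report`: `confusion` (3 x 3 matrix),
#'   `per_class` (tibble: `class`, `precision`, `recall`, `f1`, `support`),
#'   `accuracy`.
#' @export
classification_report <- function(truth, pred) {
  if (length(truth) == 0L || length(truth) != length(pred)) {
    stop("`truth` and `pred` must have equal nonzero length", call. = FALSE)
  }
  truth <- factor(as.character(truth), levels = BI_CLASS_LEVELS)
  pred <- factor(as.character(pred), levels = BI_CLASS_LEVELS)
  if (anyNA(truth) || anyNA(pred)) {
    stop("labels must be A, B, or C", call. = FALSE)
  }
  confusion <- table(true = truth, predicted = pred)
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  true_n <- rowSums(confusion)
  zero_div <- pred_n == 0 | true_n == 0
  if (any(zero_div & (true_n > 0 | pred_n > 0))) {
    warning("precision/recall undefined for some class; reporting 0.00",
            call. = FALSE)
  }
  precision <- ifelse(pred_n == 0, 0, tp / pred_n)
  recall <- ifelse(true_n == 0, 0, tp / true_n)
  structure(
    list(
      confusion = unclass(confusion),
      per_class = tibble::tibble(
        class = BI_CLASS_LEVELS,
        precision = as.numeric(precision),
        recall = as.numeric(recall),
        f1 = f1_from_pr(as.numeric(precision), as.numeric(recall)),
        support = as.integer(true_n)
      ),
      accuracy = sum(tp) / length(truth)
    ),
    class = "class_report"
  )
}

#' Score a fitted tree on one dataset role
#'
#' Computes the regression metrics on the predicted BI and, after
#' converting both measured and predicted BI to dependence classes, the
#' classification report.
#'
#' @param model A fitted `bi_tree`.
#' @param data Tibble with features and the target column.
#' @param target Target column name.
#' @return List of class `bi_eval`: `n`, `regression` (mae/mad/rmse/r2),
#'   `classification` (a `class_report`), and `predictions` tibble.
#' @export
evaluate_model <- function(model, data, target = "barthel_index") {
  pred <- predict(model, data)
  truth <- as.numeric(data[[target]])
  reg <- regression_metrics(truth, pred)
  cls <- suppressWarnings(
    classification_report(bi_to_class(truth), bi_to_class(pred)))
  structure(
    list(
      n = nrow(data),
      regression = reg,
      classification = cls,
      predictions = tibble::tibble(
        patient_id = if ("patient_id" %in% names(data)) data$patient_id
                     else as.character(seq_along(truth)),
        true_bi = truth,
        predicted_bi = pred,
        true_class = bi_to_class(truth),
        predicted_class = bi_to_class(pred)
      )
    ),
    class = "bi_eval"
  )
}

#' @export
print.bi_eval <- function(x, ...) {
  cat(sprintf("Evaluation on %d records\n", x$n))
  cat(sprintf("  Accuracy  %d%%\n",
              round(100 * x$classification$accuracy)))
  cat(sprintf("  MAE       %.2f\n", x$regression$mae))
  cat(sprintf("  MAD       %.2f\n", x$regression$mad))
  cat(sprintf("  RMSE      %.2f\n", x$regression$rmse))
  cat("Per-class metrics:\n")
  pc <- x$per_class %||% x$classification$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  class %s: precision %.2f, recall %.2f, F1 %.2f (support %d)\n",
                pc$class[i], pc$precision[i], pc$recall[i], pc$f1[i],
                pc$support[i]))
  }
  invisible(x)
}

eval_to_list <- function(ev) {
  list(
    n = ev$n,
    accuracy = ev$classification$accuracy,
    accuracy_percent = round(100 * ev$classification$accuracy),
    mae = ev$regression$mae,
    mad = ev$regression$mad,
    rmse = ev$regression$rmse,
    r2 = ev$regression$r2,
    per_class = ev$classification$per_class,
    confusion = ev$classification$confusion
  )
}
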