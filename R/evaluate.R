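# Classifier evaluation: classification quality (fraction of concordant
# predictions), RMSE over the crisp one-of-5 output encoding, and per-
# partition confusion matrices.

#' Classification quality
#'
#' Fraction of cases whose predicted class equals the true class; a quality
#' of 0.9213 means 92.13% of cases classified correctly.
#'
#' @param predictions,labels Equal-length class vectors.
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' quality(c(1, 2, 3, 4), c(1, 2, 3, 5))
quality <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) == 0)
    abort("predictions and labels must be non-empty and of equal length")
  mean(predictions == labels)
}

#' Root-mean-square error
#'
#' Square root of (sum of squared errors divided by the number of included
#' values): every element of `outputs - targets` counts as one included
#' value, so for `N` cases with 5 output components the divisor is `N * 5`.
#'
#' @param outputs,targets Numeric vectors or matrices of identical shape.
#' @return Non-negative scalar.
#' @export
#' @examples
#' rmse(c(1, -1, 0, 0), c(0, 0, 0, 0))  # sqrt(2/4)
rmse <- function(outputs, targets) {
  if (!identical(dim(outputs), dim(targets)) ||
      length(outputs) != length(targets) || length(outputs) == 0)
    abort("outputs and targets must be non-empty and of identical shape")
  sqrt(mean((outputs - targets)^2))
}

#' One-of-k (one-hot) encoding of class labels
#'
#' @param classes Integer class vector.
#' @param n_classes Number of output components (default 5).
#' @return `length(classes) x n_classes` 0/1 matrix.
#' @export
one_hot <- function(classes, n_classes = 5L) {
  m <- matrix(0, length(classes), n_classes)
  m[cbind(seq_along(classes), as.integer(classes))] <- 1
  m
}

#' RMSE of crisp class predictions
#'
#' RMSE between the winner-take-all one-of-5 encodings of predictions and
#' true labels. Under this crisp encoding a misclassified case contributes
#' exactly two unit errors, giving the identity
#' `rmse = sqrt(2 (1 - quality) / 5)`.
#'
#' @inheritParams quality
#' @param n_classes Number of classes (default 5).
#' @return Non-negative scalar.
#' @export
rmse_classes <- function(predictions, labels, n_classes = 5L) {
  rmse(one_hot(predictions, n_classes), one_hot(labels, n_classes))
}

#' Confusion matrix (rows = true class, cols = predicted)
#'
#' @inheritParams rmse_classes
#' @return `n_classes x n_classes` integer matrix.
#' @export
confusion_matrix <- function(predictions, labels, n_classes = 5L) {
  m <- table(factor(labels, levels = seq_len(n_classes)),
             factor(predictions, levels = seq_len(n_classes)))
  matrix(as.integer(m), n_classes, n_classes,
         dimnames = list(true = seq_len(n_classes),
                         predicted = seq_len(n_classes)))
}

#' Evaluate a labelled map on a split feature table
#'
#' Computes quality, crisp one-of-5 RMSE, the confusion matrix and the case
#' count for each partition present among train/valid/test. Partitions
#' listed but absent are skipped with a warning.
#'
#' @param data Split tibble with feature columns, `class_id` and
#'   `partition`.
#' @param model A labelled `topo_map`.
#' @param normalise Passed to [predict.topo_map()].
#' @return A `compost_eval` object.
#' @export
evaluate_model <- function(data, model, normalise = !is.null(model$normaliser)) {
  stopifnot(all(c("class_id", "partition") %in% names(data)))
  parts <- list()
  for (p in c("train", "valid", "test")) {
    rows <- partition_rows(data, p)
    if (nrow(rows) == 0) {
      warn(paste0("partition '", p, "' is empty; skipped"))
      next
    }
    pred <- predict(model, rows, normalise = normalise)
    parts[[p]] <- list(quality = quality(pred, rows$class_id),
                       rmse = rmse_classes(pred, rows$class_id),
                       confusion = confusion_matrix(pred, rows$class_id),
                       n_cases = nrow(rows))
  }
  structure(list(partitions = parts), class = "compost_eval")
}

#' @export
print.compost_eval <- function(x, ...) {
  cat("<compost_eval>\n")
  for (p in names(x$partitions)) {
    e <- x$partitions[[p]]
    cat(sprintf("  %-5s  n = %4d  quality = %.4f  rmse = %.5f\n",
                p, e$n_cases, e$quality, e$rmse))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param report A `compost_eval`.
#' @param json_path Output path for the JSON report.
#' @param text_path Optional path for a human-readable summary.
#' @param confusion_dir Optional directory for per-partition confusion CSVs.
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path, text_path = NULL,
                              confusion_dir = NULL) {
  jsonlite::write_json(
    lapply(report$partitions, function(e)
      list(quality = e$quality, rmse = e$rmse, n_cases = e$n_cases,
           confusion = lapply(seq_len(nrow(e$confusion)),
                              function(i) unname(e$confusion[i, ])))),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  if (!is.null(confusion_dir)) {
    dir.create(confusion_dir, recursive = TRUE, showWarnings = FALSE)
    for (p in names(report$partitions))
      utils::write.csv(report$partitions[[p]]$confusion,
                       file.path(confusion_dir, paste0("confusion_", p, ".csv")))
  }
  invisible(report)
}
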