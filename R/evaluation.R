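#' Confusion matrix for binary predictions
#'
#' The positive class is post-lesion (class 1): detecting the lesion
#' effect is the clinical question, so sensitivity and precision are
#' defined with respect to post-lesion windows.
#'
#' @param predictions,truth Equal-length 0/1 vectors.
#' @return An object of class `confusion_matrix`: list with `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion <- function(predictions, truth) {
  predictions <- check_binary_labels(predictions, "predictions")
  truth <- check_binary_labels(truth, "truth")
  if (length(predictions) != length(truth)) {
    stop_invalid("predictions and truth must have the same length")
  }
  structure(
    list(tp = sum(predictions == 1L & truth == 1L),
         fp = sum(predictions == 1L & truth == 0L),
         tn = sum(predictions == 0L & truth == 0L),
         fn = sum(predictions == 0L & truth == 1L)),
    class = "confusion_matrix"
  )
}

#' The five classification performance metrics
#'
#' Accuracy, sensitivity (recall of the post-lesion class), specificity,
#' precision and F-measure (harmonic mean of precision and sensitivity),
#' all reported as percentages. A ratio with a zero denominator is
#' reported as 0 with a warning rather than propagating `NaN`.
#'
#' @param cm A [confusion()] matrix.
#' @return Named numeric vector `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f_measure`, each in `[0, 100]`.
#' @export
#' @examples
#' classification_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1)))
classification_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop_invalid("cm must be a confusion_matrix")
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  acc <- safe_ratio(cm$tp + cm$tn, n, "accuracy")
  sens <- safe_ratio(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe_ratio(cm$tn, cm$tn + cm$fp, "specificity")
  prec <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  f <- if (prec + sens == 0) {
    warning("F-measure undefined (zero denominator); reported as 0", call. = FALSE)
    0
  } else {
    2 * prec * sens / (prec + sens)
  }
  100 * c(accuracy = acc, sensitivity = sens, specificity = spec,
          precision = prec, f_measure = f)
}

#' Stratified k-fold cross-validation
#'
#' Partitions the dataset into `k` disjoint, exhaustive folds,
#' stratified by class at the segment level; each fold serves once as
#' the test set while the classifier recipe is fitted on the remainder.
#'
#' @param fit_predict Function `(train_dataset, test_dataset) ->
#'   integer predictions for the test rows` encapsulating one classifier
#'   arm (feature extraction + kNN, or CNN training + prediction).
#' @param dataset A [segment_dataset()]; each class must have at least
#'   `k` segments.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `evaluation_report`: list with `per_fold`
#'   (data frame of the five metrics per fold), `mean`, `sd` and `folds`
#'   (the index partition).
#' @export
kfold_cv <- function(fit_predict, dataset, k = 5L, seed = 1) {
  if (!inherits(dataset, "segment_dataset")) {
    stop_invalid("dataset must be a segment_dataset")
  }
  k <- check_count(k, "k", 2L)
  labels <- dataset$labels
  folds <- integer(length(labels))
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      stop_invalid("class ", cls, " has fewer than k = ", k, " segments")
    }
    shuffled <- with_seed(derive_seed(seed, paste0("fold_", cls)), sample(idx))
    folds[shuffled] <- rep_len(seq_len(k), length(idx))
  }
  subset_sd <- function(idx) {
    segment_dataset(dataset$segments[idx, , drop = FALSE], labels[idx],
                    dataset$source[idx, , drop = FALSE])
  }
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    preds <- fit_predict(subset_sd(train_idx), subset_sd(test_idx))
    m <- classification_metrics(confusion(preds, labels[test_idx]))
    per_fold[[f]] <- data.frame(fold = f, t(m))
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- setdiff(names(per_fold), "fold")
  structure(
    list(per_fold = per_fold,
         mean = colMeans(per_fold[metric_cols]),
         sd = apply(per_fold[metric_cols], 2L, stats::sd),
         folds = folds),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d folds\n", nrow(x$per_fold)))
  cat("mean metrics (%):\n")
  print(round(x$mean, 2))
  invisible(x)
}

#' Side-by-side comparison of classifier reports
#'
#' Writes a tidy CSV of the five metrics for each classifier (per fold
#' and mean rows) and a grouped bar plot of the mean metrics, the usual
#' way the two arms of the comparison are presented.
#'
#' @param reports Named list of `evaluation_report` objects (e.g.
#'   `list(knn = ..., cnn = ...)`); entries that are `NULL` are dropped
#'   with a note in the CSV.
#' @param out_dir Output directory (created if absent).
#' @param side Optional side tag written into the table.
#' @return Invisible list with the `table` data frame and output paths.
#' @export
compare_report <- function(reports, out_dir, side = NA_character_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  missing <- names(reports)[vapply(reports, is.null, logical(1))]
  reports <- reports[!vapply(reports, is.null, logical(1))]
  if (length(reports) == 0L) stop_invalid("no reports to compare")
  rows <- lapply(names(reports), function(nm) {
    rep_ <- reports[[nm]]
    per <- cbind(classifier = nm, side = side, rep_$per_fold)
    mean_row <- data.frame(classifier = nm, side = side, fold = "mean",
                           t(rep_$mean))
    names(mean_row) <- names(per)
    rbind(per, mean_row)
  })
  tab <- do.call(rbind, rows)
  csv_path <- file.path(out_dir, "metrics_comparison.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE)
  if (length(missing)) {
    writeLines(paste("note: no report for:", paste(missing, collapse = ", ")),
               file.path(out_dir, "metrics_comparison_note.txt"))
  }
  plot_path <- file.path(out_dir, "metrics_comparison.png")
  means <- do.call(rbind, lapply(reports, `[[`, "mean"))
  grDevices::png(plot_path, width = 720, height = 420)
  graphics::barplot(means, beside = TRUE, ylim = c(0, 100),
                    legend.text = rownames(means),
                    ylab = "metric (%)",
                    main = if (is.na(side)) "Classifier comparison"
                           else paste("Classifier comparison -", side))
  grDevices::dev.off()
  invisible(list(table = tab, csv = csv_path, plot = plot_path))
}
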