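#' Fit a k-nearest-neighbours classifier
#'
#' kNN is a lazy learner: fitting just stores the training feature rows
#' and labels. Prediction votes among the `k` nearest stored rows. The
#' default `k = 9` is odd, so a binary majority vote can never tie.
#'
#' @param features Numeric matrix of training feature rows (the kNN arm
#'   uses the 4 scaled amplitude features).
#' @param labels 0/1 labels, one per row.
#' @param k Number of neighbours, `1 <= k <= nrow(features)`.
#' @return An object of class `knn_model`.
#' @export
#' @examples
#' m <- knn_fit(matrix(c(0, 0, 0, 0, 5, 5, 0, 0), 2, byrow = TRUE), c(0, 1), k = 1)
#' knn_predict(m, matrix(c(1, 0, 0, 0), 1))
knn_fit <- function(features, labels, k = 9L) {
  if (!is.matrix(features)) features <- as.matrix(features)
  labels <- check_binary_labels(labels)
  if (nrow(features) != length(labels)) {
    stop_invalid("features and labels must have the same number of rows")
  }
  k <- check_count(k, "k", lower = 1L)
  if (k > nrow(features)) {
    stop_invalid("k = ", k, " exceeds the number of training rows (", nrow(features), ")")
  }
  structure(
    list(train_points = features, train_labels = labels, k = k,
         metric = "euclidean"),
    class = "knn_model"
  )
}

#' Predict with a fitted kNN model
#'
#' Exact brute-force neighbour search (all pairwise Euclidean distances;
#' no tree index — exact and fast at this problem scale). For each query
#' the majority label among the `k` nearest training rows wins; equal
#' distances are broken in favour of the lower training-row index, and
#' `k` odd makes vote ties impossible.
#'
#' @param model A [knn_fit()] model.
#' @param queries Numeric matrix of query rows with the same number of
#'   columns as the training features.
#' @return Integer vector of predicted 0/1 labels.
#' @export
knn_predict <- function(model, queries) {
  if (!inherits(model, "knn_model")) stop_invalid("model must be a knn_model")
  if (!is.matrix(queries)) queries <- matrix(queries, nrow = 1L)
  train <- model$train_points
  if (ncol(queries) != ncol(train)) {
    stop_invalid("queries have ", ncol(queries), " columns but the model expects ",
                 ncol(train))
  }
  # squared distances via the expansion |q - t|^2 = |q|^2 + |t|^2 - 2 q.t
  tn <- rowSums(train^2)
  qn <- rowSums(queries^2)
  d2 <- outer(qn, tn, "+") - 2 * queries %*% t(train)
  d2[d2 < 0] <- 0
  k <- model$k
  preds <- integer(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    # order() is stable: exact-distance ties resolve to the lower index
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- sum(model$train_labels[nn])
    preds[i] <- if (votes * 2L > k) 1L else 0L
  }
  preds
}
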