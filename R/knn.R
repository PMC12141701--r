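## k-nearest-neighbour engine shared by the INCA loss generator and the tkNN
## ensemble. Distances: cityblock (L1), euclidean (L2), cosine
## (1 - cosine similarity) and spearman (1 - Spearman rank correlation of
## the feature vectors). Vote weights: equal, inverse (1/d),
## squared_inverse (1/d^2); exact matches (d = 0) dominate the vote alone.

KNN_DISTANCES <- c("cityblock", "euclidean", "cosine", "spearman")
KNN_WEIGHTS <- c("squared_inverse", "equal", "inverse")

## test x train cross-distance matrix
cross_distances <- function(test, train, distance) {
  test <- as.matrix(test); train <- as.matrix(train)
  switch(distance,
    cityblock = {
      t(apply(test, 1L, function(x) colSums(abs(t(train) - x))))
    },
    euclidean = {
      cp <- tcrossprod(test, train)
      d2 <- outer(rowSums(test^2), rowSums(train^2), "+") - 2 * cp
      sqrt(pmax(d2, 0))
    },
    cosine = {
      nt <- sqrt(rowSums(test^2)); nr <- sqrt(rowSums(train^2))
      sim <- tcrossprod(test, train) / outer(nt, nr)
      sim[!is.finite(sim)] <- 0   # zero vectors: similarity defined as 0
      1 - sim
    },
    spearman = {
      rt <- t(apply(test, 1L, rank)); rr <- t(apply(train, 1L, rank))
      if (ncol(test) == 1L) { rt <- t(rt); rr <- t(rr) }
      suppressWarnings(rho <- stats::cor(t(rt), t(rr)))
      rho[!is.finite(rho)] <- 0   # zero-variance rows: correlation defined as 0
      1 - rho
    },
    stop("value error: unknown distance '", distance, "'", call. = FALSE)
  )
}

## smallest label among the maximizers of a named score vector
argmax_smallest_label <- function(scores, levels) {
  levels[which(scores == max(scores))[1]]
}

#' k-nearest-neighbour prediction
#'
#' Predicts each test row from its `k` nearest training rows under the given
#' distance, with distance-based vote weights. Exact matches dominate: if
#' any of a test row's training points lie at distance zero, their classes
#' decide alone with equal weight. Vote ties go to the smallest class label;
#' distance ties keep training order.
#'
#' @param train_features,test_features Numeric matrices with the same column
#'   count.
#' @param train_labels Class labels for the training rows.
#' @param distance One of `"cityblock"`, `"euclidean"`, `"cosine"`,
#'   `"spearman"`.
#' @param weight One of `"equal"`, `"inverse"`, `"squared_inverse"`.
#' @param k Neighbourhood size, `1 <= k <= nrow(train_features)`.
#' @return Vector of predicted labels, one per test row, of the same type as
#'   `train_labels`.
#' @export
knn_predict <- function(train_features, train_labels, test_features,
                        distance = "cityblock", weight = "equal", k = 1L) {
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  distance <- match.arg(distance, KNN_DISTANCES)
  weight <- match.arg(weight, c("equal", "inverse", "squared_inverse"))
  n_train <- nrow(train_features)
  if (k < 1L || k > n_train) {
    stop("value error: k must lie in [1, number of training rows]", call. = FALSE)
  }
  if (ncol(train_features) != ncol(test_features)) {
    stop("dimension error: train and test feature widths differ", call. = FALSE)
  }
  if (!all(is.finite(train_features)) || !all(is.finite(test_features))) {
    stop("value error: non-finite features", call. = FALSE)
  }
  levels <- sort(unique(train_labels))
  D <- cross_distances(test_features, train_features, distance)
  D <- matrix(D, nrow = nrow(test_features))   # guard 1-row drop
  pred <- vector(mode = typeof(train_labels), nrow(D))
  for (i in seq_len(nrow(D))) {
    d <- D[i, ]
    ord <- order(d)[seq_len(k)]
    dk <- d[ord]
    lk <- train_labels[ord]
    if (any(dk <= 0)) {       # exact matches decide alone
      zl <- train_labels[d <= 0]
      scores <- vapply(levels, function(lv) sum(zl == lv), 0)
    } else {
      w <- switch(weight, equal = rep(1, k), inverse = 1 / dk,
                  squared_inverse = 1 / dk^2)
      scores <- vapply(levels, function(lv) sum(w[lk == lv]), 0)
    }
    pred[i] <- argmax_smallest_label(scores, levels)
  }
  pred
}

## Out-of-fold predictions for one kNN configuration under a CV partition.
cv_knn_predictions <- function(features, labels, fold_of,
                               distance = "cityblock", weight = "equal",
                               k = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(fold_of) != n) {
    stop("partition error: fold assignment length differs from sample count",
         call. = FALSE)
  }
  pred <- vector(mode = typeof(labels), n)
  for (f in sort(unique(fold_of))) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    if (!length(train_idx)) {
      stop("partition error: fold ", f, " leaves an empty training set",
           call. = FALSE)
    }
    kk <- min(k, length(train_idx))
    pred[test_idx] <- knn_predict(
      features[train_idx, , drop = FALSE], labels[train_idx],
      features[test_idx, , drop = FALSE],
      distance = distance, weight = weight, k = kk
    )
  }
  pred
}
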