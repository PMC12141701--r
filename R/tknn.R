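## tkNN: an ensemble kNN. A 4 x 3 x 10 grid of (distance, weight, k)
## configurations yields 120 out-of-fold prediction vectors; iterative
## majority voting over the accuracy-sorted top m = 3..120 outcomes adds
## 118 voted vectors; a greedy pass keeps the most accurate of all 238.

#' The tkNN configuration grid
#'
#' Enumerates all 120 = 4 x 3 x 10 combinations of distance metric
#' (cityblock, euclidean, cosine, spearman), vote weight (squared inverse,
#' equal, inverse) and k = 1..10, distance-major, then weight, then k.
#'
#' @return Data frame with columns `distance`, `weight`, `k` (120 rows).
#' @export
knn_config_grid <- function() {
  grid <- expand.grid(k = 1:10, weight = KNN_WEIGHTS, distance = KNN_DISTANCES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid[, c("distance", "weight", "k")]
}

## element-wise mode over the rows of a label matrix; ties -> smallest label
vote_mode <- function(votes, levels) {
  counts <- vapply(levels, function(lv) colSums(votes == lv),
                   numeric(ncol(votes)))
  counts <- matrix(counts, ncol = length(levels))
  levels[max.col(counts, ties.method = "first")]
}

#' Out-of-fold outcomes for every tkNN grid configuration
#'
#' For each of the 120 grid configurations, assembles held-out predictions
#' across the folds of `fold_of` into one length-n outcome vector and scores
#' it against the true labels (accuracy in percent).
#'
#' @param features Numeric matrix, n x r.
#' @param labels True class labels.
#' @param fold_of Integer fold assignment per row.
#' @return List with `predictions` (n x 120 matrix, one column per config),
#'   `accuracies` (120 values in \[0, 100\]) and `configs` (the grid).
#' @export
parameter_outcomes <- function(features, labels, fold_of) {
  grid <- knn_config_grid()
  preds <- vapply(seq_len(nrow(grid)), function(e) {
    cv_knn_predictions(features, labels, fold_of,
                       distance = grid$distance[e], weight = grid$weight[e],
                       k = grid$k[e])
  }, vector(mode = typeof(labels), length(labels)))
  acc <- 100 * colMeans(preds == labels)
  list(predictions = preds, accuracies = acc, configs = grid)
}

#' Iterative majority voting over accuracy-sorted outcomes
#'
#' Sorts the outcome vectors by accuracy descending (stable: ties keep
#' enumeration order) and, for l = 1..(m - 2), takes the element-wise mode
#' of the top (l + 2) sorted outcomes. Mode ties go to the smallest class
#' label. With the full 120-outcome grid this yields 118 voted vectors
#' (vote sizes 3..120).
#'
#' @param predictions n x m matrix of outcome vectors (m >= 3).
#' @param accuracies Their m accuracies (percent).
#' @param labels True labels, used to score the voted outcomes.
#' @return List with `predictions` (n x (m - 2) voted matrix), `accuracies`
#'   (length m - 2), and `sorted_order` (the accuracy-descending index).
#' @export
iterative_majority_vote <- function(predictions, accuracies, labels) {
  predictions <- as.matrix(predictions)
  m <- ncol(predictions)
  if (m < 3L) stop("value error: need at least 3 outcomes to vote", call. = FALSE)
  ix <- order(-accuracies, seq_len(m))   # stable descending sort
  levels <- sort(unique(labels))
  sorted <- predictions[, ix, drop = FALSE]
  voted <- vapply(seq_len(m - 2L), function(l) {
    vote_mode(t(sorted[, seq_len(l + 2L), drop = FALSE]), levels)
  }, vector(mode = typeof(labels), length(labels)))
  voted <- matrix(voted, nrow = nrow(predictions))
  list(predictions = voted,
       accuracies = 100 * colMeans(voted == labels),
       sorted_order = ix)
}

#' Greedy best-outcome selection
#'
#' Returns the outcome with maximal accuracy from the pooled candidate set;
#' ties go to the smallest index (parameter outcomes precede voted ones).
#'
#' @param predictions n x M matrix of pooled candidate outcomes.
#' @param accuracies Their M accuracies.
#' @return List with `best_predictions`, `best_index`, `best_accuracy`.
#' @export
greedy_best <- function(predictions, accuracies) {
  predictions <- as.matrix(predictions)
  idx <- which.max(accuracies)   # first maximum = smallest index
  list(best_predictions = predictions[, idx],
       best_index = idx,
       best_accuracy = accuracies[idx])
}

#' The tkNN ensemble classifier
#'
#' Composition of [parameter_outcomes()], [iterative_majority_vote()] and
#' [greedy_best()]: 120 parameter-based outcomes, 118 voted outcomes, and
#' the greedy choice among all 238. Fully deterministic given the fold
#' assignment.
#'
#' @inheritParams parameter_outcomes
#' @return Object of class `outcome_set`: list with `parameter_predictions`
#'   (n x 120), `voted_predictions` (n x 118), `accuracies` (238 values,
#'   percent), `configs`, `sorted_order`, `best_index`, `best_accuracy` and
#'   `best_predictions` (the selected length-n outcome).
#' @export
tknn <- function(features, labels, fold_of) {
  pout <- parameter_outcomes(features, labels, fold_of)
  vout <- iterative_majority_vote(pout$predictions, pout$accuracies, labels)
  pool_pred <- cbind(pout$predictions, vout$predictions)
  pool_acc <- c(pout$accuracies, vout$accuracies)
  best <- greedy_best(pool_pred, pool_acc)
  structure(
    list(parameter_predictions = pout$predictions,
         voted_predictions = vout$predictions,
         accuracies = pool_acc,
         configs = pout$configs,
         sorted_order = vout$sorted_order,
         best_index = best$best_index,
         best_accuracy = best$best_accuracy,
         best_predictions = best$best_predictions),
    class = "outcome_set"
  )
}

#' @export
print.outcome_set <- function(x, ...) {
  kind <- if (x$best_index <= ncol(x$parameter_predictions)) {
    cfg <- x$configs[x$best_index, ]
    sprintf("parameter outcome (%s/%s/k=%d)", cfg$distance, cfg$weight, cfg$k)
  } else {
    sprintf("voted outcome (top-%d vote)",
            x$best_index - ncol(x$parameter_predictions) + 2L)
  }
  cat(sprintf("<outcome_set> %d candidates; best #%d = %s, accuracy %.2f%%\n",
              length(x$accuracies), x$best_index, kind, x$best_accuracy))
  invisible(x)
}
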