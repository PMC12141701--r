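## Diagonal (per-feature) neighbourhood component analysis.
##
## The classical NCA learns a full linear transform; for feature *selection*
## a diagonal variant is used: a per-feature weight vector w enters a
## weighted L1 distance d_w(x_i, x_j) = sum_r w_r^2 |x_ir - x_jr| and the
## leave-one-out soft-neighbour objective
##   F(w) = (1/n) sum_i sum_{j != i, y_j = y_i} p_ij  -  lambda sum_r w_r^2,
##   p_ij = exp(-d_w(x_i, x_j) / sigma) / sum_{k != i} exp(-d_w(x_i, x_k) / sigma)
## is maximized by deterministic full-batch gradient ascent with step
## halving. Features are z-scored internally; the kernel length scale sigma
## is fixed to the mean pairwise distance at the all-ones initialization so
## the soft-neighbour kernel is well conditioned for any feature count.

#' Per-feature NCA relevance weights
#'
#' Maximizes the regularized leave-one-out soft-neighbour objective with a
#' diagonal weight vector and returns the squared weights as non-negative
#' per-feature relevance scores. Deterministic: the all-ones initialization
#' and full-batch line-halving ascent involve no randomness; `seed` is
#' accepted for interface symmetry and recorded, not consumed.
#'
#' @param features Numeric matrix, n samples x p features.
#' @param labels Class labels (at least two classes present).
#' @param regularization Non-negative ridge penalty lambda; default `1/n`.
#' @param max_iter Iteration cap for the ascent (default 100).
#' @param seed Integer, recorded in the result attributes.
#' @return Non-negative numeric vector of p relevance weights, with
#'   attributes `objective` (final objective value) and `iterations`.
#' @export
nca_weights <- function(features, labels, regularization = NULL,
                        max_iter = 100L, seed = 1L) {
  x <- as.matrix(features)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("dimension error: need at least 2 samples", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("degenerate-label error: need at least two classes", call. = FALSE)
  }
  if (is.null(regularization)) regularization <- 1 / n
  if (regularization < 0) stop("value error: regularization must be >= 0", call. = FALSE)

  ## internal z-scoring; constant features stay constant (scale 1)
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd == 0] <- 1
  x <- sweep(sweep(x, 2L, mu), 2L, sd, "/")

  same <- outer(labels, labels, "==")
  diag(same) <- FALSE

  ## |x_i - x_j| over all ordered pairs, flattened (n*n) x p; row ij = (i, j)
  A <- abs(x[rep(seq_len(n), each = n), , drop = FALSE] -
           x[rep(seq_len(n), times = n), , drop = FALSE])

  obj_grad <- function(w, sigma) {
    w2 <- w^2
    d <- matrix(A %*% w2, n, n, byrow = TRUE)   # d[i, j]
    diag(d) <- Inf
    e <- exp(-(d - apply(d, 1L, min)) / sigma)  # shift-invariant softmax
    diag(e) <- 0
    pij <- e / rowSums(e)
    pi_ <- rowSums(pij * same)
    objective <- mean(pi_) - regularization * sum(w2)
    coef <- pij * (pi_ - same)                  # c_ij = p_ij (p_i - 1[same])
    coef_flat <- as.vector(t(coef))             # match A's (i, j) row order
    grad <- (2 * w / (n * sigma)) * as.vector(crossprod(A, coef_flat)) -
      2 * regularization * w
    list(objective = objective, grad = grad)
  }

  ## kernel length scale: the spread of pairwise distances at the all-ones
  ## start, i.e. the scale on which neighbours actually differ — a mean-based
  ## scale leaves the softmax nearly uniform for large p and the ridge term
  ## then collapses every weight to zero
  w <- rep(1, p)
  d0 <- matrix(A %*% w^2, n, n, byrow = TRUE)
  sigma <- stats::sd(d0[row(d0) != col(d0)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1

  og <- obj_grad(w, sigma)
  eta <- 1
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    accepted <- FALSE
    for (h in 1:30) {
      ## projected ascent: relevance is w^2, so w is kept non-negative —
      ## otherwise an overshoot through zero leaves an irrelevant feature
      ## with a large squared weight
      w_new <- pmax(w + eta * og$grad, 0)
      og_new <- obj_grad(w_new, sigma)
      if (is.finite(og_new$objective) && og_new$objective > og$objective) {
        w <- w_new; og <- og_new; eta <- eta * 1.2; accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted || sqrt(sum(og$grad^2)) < 1e-8) break
  }
  structure(w^2, objective = og$objective, iterations = iters, seed = seed)
}

#' Rank features by relevance weight
#'
#' @param weights Numeric vector of per-feature weights.
#' @return Integer permutation of `seq_along(weights)`: indices sorted by
#'   weight descending, ties broken by ascending index.
#' @export
#' @examples
#' rank_features(c(0.1, 0.9, 0.5))  # 2 3 1
rank_features <- function(weights) {
  if (!length(weights)) stop("dimension error: empty weight vector", call. = FALSE)
  order(-as.numeric(weights), seq_along(weights))
}

#' Misclassification rate of a 1-NN city-block classifier under CV
#'
#' The loss generator of the iterative selector: held-out predictions from a
#' 1-nearest-neighbour classifier with L1 distance and equal weights,
#' assembled across the folds of `fold_of`; the loss is the misclassified
#' fraction.
#'
#' @param features Numeric matrix, n x r.
#' @param labels Class labels.
#' @param fold_of Integer fold assignment per row (e.g. from
#'   [make_partition()]).
#' @param k,distance,weight kNN settings; defaults k = 1, L1, equal weights.
#' @return Misclassification rate in `[0, 1]`.
#' @export
knn_loss <- function(features, labels, fold_of,
                     k = 1L, distance = "cityblock", weight = "equal") {
  pred <- cv_knn_predictions(features, labels, fold_of,
                             distance = distance, weight = weight, k = k)
  mean(pred != labels)
}

#' Iterative NCA feature selection
#'
#' Ranks all features by [nca_weights()], then for every subset size `r`
#' in `start:stop` evaluates the CV misclassification of the top-`r` ranked
#' features with [knn_loss()] and keeps the loss-minimizing size (ties go to
#' the smallest `r`).
#'
#' @param features Numeric matrix, n x p with `p >= stop` (otherwise `stop`
#'   is clipped to p with a warning).
#' @param labels Class labels.
#' @param start,stop Subset-size range (defaults 14 and 98).
#' @param seed Integer seed driving the internal stratified tenfold loss
#'   partition.
#' @param n_folds Folds for the internal loss CV (default 10).
#' @param regularization,max_iter Passed to [nca_weights()].
#' @return Object of class `selection_result`: list with `ranked_indices`,
#'   `weights`, `loss_curve` (named by r), `chosen_r`, `chosen_indices`,
#'   `n_selected`, `start`, `stop`, `seed`.
#' @export
inca_select <- function(features, labels, start = 14L, stop = 98L, seed = 1L,
                        n_folds = 10L, regularization = NULL, max_iter = 100L) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (stop > p) {
    warning(sprintf("stop = %d exceeds feature count %d; clipped", stop, p))
    stop <- p
  }
  if (start > stop) stop("value error: start exceeds stop", call. = FALSE)
  if (start < 1L) stop("value error: start must be >= 1", call. = FALSE)

  w <- nca_weights(features, labels, regularization = regularization,
                   max_iter = max_iter, seed = seed)
  ranked <- rank_features(w)

  fold_of <- make_partition(labels, scheme = "tenfold", seed = seed,
                            n_folds = n_folds)$fold_of
  rs <- start:stop
  loss <- vapply(rs, function(r) {
    knn_loss(features[, ranked[seq_len(r)], drop = FALSE], labels, fold_of)
  }, numeric(1))
  names(loss) <- rs

  chosen_r <- rs[which.min(loss)]   # which.min takes the first minimum
  structure(
    list(ranked_indices = ranked,
         weights = as.numeric(w),
         loss_curve = loss,
         chosen_r = chosen_r,
         chosen_indices = ranked[seq_len(chosen_r)],
         n_selected = chosen_r,
         start = start, stop = stop, seed = seed),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> chose %d of %d features (loss %.4f) over r in [%d, %d]\n",
              x$chosen_r, length(x$ranked_indices), min(x$loss_curve),
              x$start, x$stop))
  invisible(x)
}
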