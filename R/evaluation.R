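## Cross-validation partitions, mode fusion across the three feature
## branches, greedy final selection, and the standard two-class metrics.

#' Build a cross-validation partition
#'
#' Two schemes:
#' \describe{
#'   \item{`tenfold`}{Class-stratified k-fold (default 10). Within each
#'     class, samples are shuffled (seeded) and dealt round-robin, so fold
#'     sizes differ by at most one overall and per class.}
#'   \item{`loro`}{Leave-one-record-out: one fold per distinct record id, so
#'     no recording session ever spans the train/test split.}
#' }
#'
#' @param labels Class labels, one per segment.
#' @param record_ids Record id per segment; required for `"loro"`.
#' @param scheme `"tenfold"` or `"loro"`.
#' @param seed Integer seed for the stratified shuffle (ignored by `loro`).
#' @param n_folds Fold count for `"tenfold"` (default 10).
#' @return Object of class `cv_partition`: list with `fold_of` (integer per
#'   segment), `n_folds`, `scheme`, `seed`, and `groups` (record ids, loro).
#' @export
make_partition <- function(labels, record_ids = NULL,
                           scheme = c("tenfold", "loro"), seed = 1L,
                           n_folds = 10L) {
  scheme <- match.arg(scheme)
  n <- length(labels)
  if (scheme == "loro") {
    if (is.null(record_ids)) {
      stop("partition error: loro requires record ids", call. = FALSE)
    }
    ids <- sort(unique(as.character(record_ids)))
    if (length(ids) < 2L) {
      stop("partition error: loro requires at least 2 distinct records",
           call. = FALSE)
    }
    fold_of <- match(as.character(record_ids), ids)
    return(structure(list(fold_of = fold_of, n_folds = length(ids),
                          scheme = scheme, seed = seed, groups = record_ids),
                     class = "cv_partition"))
  }
  if (n < n_folds) {
    stop("partition error: fewer samples than folds", call. = FALSE)
  }
  fold_of <- integer(n)
  with_seed(seed, {
    pos <- 0L   # continue the fold cycle across classes: overall sizes differ <= 1
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((pos + seq_along(idx) - 1L) %% n_folds) + 1L
      pos <- pos + length(idx)
    }
  })
  structure(list(fold_of = fold_of, n_folds = n_folds, scheme = scheme,
                 seed = seed, groups = NULL),
            class = "cv_partition")
}

## evaluate an expression under a seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  state <- if (has_state) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) assign(".Random.seed", state, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Mode fusion of the three branch outcomes
#'
#' Element-wise mode of the three branch prediction vectors. With two
#' classes and three voters a strict majority always exists; with more
#' classes, ties go to the smallest label.
#'
#' @param t1,t2,t3 Equal-length prediction vectors.
#' @return Fused prediction vector.
#' @export
fuse_mode <- function(t1, t2, t3) {
  if (length(t1) != length(t2) || length(t2) != length(t3)) {
    stop("dimension error: prediction vectors differ in length", call. = FALSE)
  }
  levels <- sort(unique(c(t1, t2, t3)))
  vote_mode(rbind(t1, t2, t3), levels)
}

#' Greedy final-outcome selection
#'
#' Picks the most accurate of the three branch outcomes and the fused
#' outcome; ties go in the order (t1, t2, t3, vot).
#'
#' @param t1,t2,t3 Branch prediction vectors.
#' @param vot Fused prediction vector from [fuse_mode()].
#' @param labels True labels.
#' @return List with `predictions` (the winning vector), `which` (one of
#'   `"t1"`, `"t2"`, `"t3"`, `"vot"`) and `accuracies` (all four, percent).
#' @export
greedy_final <- function(t1, t2, t3, vot, labels) {
  cand <- list(t1 = t1, t2 = t2, t3 = t3, vot = vot)
  acc <- vapply(cand, function(p) 100 * mean(p == labels), numeric(1))
  best <- which.max(acc)
  list(predictions = cand[[best]], which = names(cand)[best], accuracies = acc)
}

#' Two-class performance metrics
#'
#' Confusion counts and the four standard rates, in percent: accuracy
#' (TP + TN) / n, sensitivity TP / (TP + FN), specificity TN / (TN + FP),
#' and their geometric mean sqrt(sensitivity x specificity).
#'
#' @param predictions Predicted labels.
#' @param labels True labels; both classes must be present.
#' @param positive_class The label counted as positive (default: smallest
#'   label, e.g. class 1 = violence in the two-class montage datasets).
#' @return Object of class `metrics_report`: list with `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `sensitivity`, `specificity`, `geometric_mean` (all
#'   rates in percent) and `positive_class`.
#' @export
compute_metrics <- function(predictions, labels,
                            positive_class = sort(unique(labels))[1]) {
  if (length(predictions) != length(labels)) {
    stop("dimension error: predictions and labels differ in length", call. = FALSE)
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("undefined-metric error: both classes must be present in the labels",
         call. = FALSE)
  }
  if (!positive_class %in% classes) {
    stop("value error: positive_class not among the labels", call. = FALSE)
  }
  pos <- labels == positive_class
  ppos <- predictions == positive_class
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
  sen <- 100 * tp / (tp + fn)
  spe <- 100 * tn / (tn + fp)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
         sensitivity = sen, specificity = spe,
         geometric_mean = sqrt(sen * spe),
         positive_class = positive_class),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics> acc %.2f  sen %.2f  spe %.2f  gm %.2f  (TP %d FP %d TN %d FN %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$geometric_mean,
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
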