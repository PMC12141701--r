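## Shared fixtures and independent brute-force oracles.

## independent oracle for the per-sample pair encoder: enumerate every
## unordered channel pair, compute sqrt(ch_i^2 + ch_j^2) directly, take the
## first minimizing / maximizing pair in (i, j), i < j scan order
brute_encode_sample <- function(column) {
  nc <- length(column)
  best_min <- NULL; best_max <- NULL
  dmin <- Inf; dmax <- -Inf
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      d <- sqrt(column[i]^2 + column[j]^2)
      if (d < dmin) { dmin <- d; best_min <- c(i, j) }
      if (d > dmax) { dmax <- d; best_max <- c(i, j) }
    }
  }
  c(val_min = (best_min[1] - 1L) * nc + (best_min[2] - 1L),
    val_max = (best_max[1] - 1L) * nc + (best_max[2] - 1L))
}

## independent oracle for one kNN test point: explicit distance formulas,
## explicit weight accumulation, smallest-label tie break
brute_knn_one <- function(train, labels, x, distance, weight, k) {
  d <- apply(train, 1L, function(r) {
    switch(distance,
      cityblock = sum(abs(r - x)),
      euclidean = sqrt(sum((r - x)^2)),
      cosine = 1 - sum(r * x) / (sqrt(sum(r^2)) * sqrt(sum(x^2))),
      spearman = 1 - suppressWarnings(stats::cor(rank(r), rank(x),
                                                 method = "pearson"))
    )
  })
  d[!is.finite(d)] <- 1
  ord <- order(d)[seq_len(k)]
  if (any(d[ord] <= 0)) {
    votes <- table(labels[d <= 0])
  } else {
    w <- switch(weight, equal = rep(1, k), inverse = 1 / d[ord],
                squared_inverse = 1 / d[ord]^2)
    votes <- tapply(w, labels[ord], sum)
    votes <- votes[!is.na(votes)]
  }
  lv <- sort(names(votes))
  votes <- votes[lv]
  as.numeric(lv[which(votes == max(votes))[1]])
}

## tiny deterministic two-cluster dataset: class 1 near the origin,
## class 2 shifted, perfectly separable
make_clusters <- function(n_per_class = 10, p = 3, shift = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, sd = 0.5), ncol = p),
             matrix(rnorm(n_per_class * p, sd = 0.5) + shift, ncol = p))
  list(x = x, y = rep(c(1, 2), each = n_per_class))
}

## small synthetic EEG dataset sized for fast end-to-end unit tests
small_dataset <- function(seed = 1, null = FALSE, records_per_class = 3,
                          segments_per_record = 4) {
  profiles <- if (null) list(rep(1, 14), rep(1, 14)) else NULL
  generate_dataset(synth_config(records_per_class = records_per_class,
                                segments_per_record = segments_per_record,
                                class_gain_profiles = profiles, seed = seed))
}

## 42-symbol reference lobe string (published explainability output for the
## min-distance branch); its symbol counts are hand-countable:
## FR 20, PL 5, OR 5, OL 5, FL 3, TR 2, PR 2
reference_dlob_string_1 <- function() {
  strsplit(paste(
    "TR PL OR OR PL PL FR OL FL FL FR OL FR FR FR OR FR PL OR OL FR",
    "OL FR PL FR FR FR FR FR FR FR FR FR FR TR OR FR FL FR PR PR OL"
  ), " ")[[1]]
}
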