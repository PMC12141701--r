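## DMPat: per-sample channel-pair distance pattern encoder.
##
## At every time point the pairwise "distance" d(i, j) = sqrt(ch_i^2 + ch_j^2)
## is evaluated over all channel pairs i < j; the codes of the minimizing and
## maximizing pairs, val = (a1-1)*NC + (a2-1), are collected over the segment
## and histogrammed into NC^2-bin feature vectors.

#' Channel-pair distance
#'
#' The instantaneous pair distance `sqrt(ch_i^2 + ch_j^2)`: the Euclidean
#' norm of the two channel amplitudes at one time point. Symmetric and
#' non-negative.
#'
#' @param ch_i,ch_j Channel amplitudes (vectorized).
#' @return Non-negative distance(s).
#' @export
#' @examples
#' pair_distance(3, 4)  # 5
pair_distance <- function(ch_i, ch_j) {
  if (!all(is.finite(ch_i), is.finite(ch_j))) {
    stop("value error: non-finite amplitudes", call. = FALSE)
  }
  sqrt(ch_i^2 + ch_j^2)
}

## Upper-triangle pair list in row-major scan order: (1,2), (1,3), ...,
## (1,NC), (2,3), ... This order is the tie-break: the first extremal pair
## in the scan wins.
pair_index_table <- function(nc) {
  a1 <- rep.int(seq_len(nc - 1L), times = (nc - 1L):1L)
  a2 <- unlist(lapply(seq_len(nc - 1L), function(i) (i + 1L):nc), use.names = FALSE)
  cbind(a1 = a1, a2 = a2)
}

encode_pair <- function(a1, a2, nc) unname((a1 - 1L) * nc + (a2 - 1L))

#' Encode one multichannel sample as min/max pair codes
#'
#' Over all ordered channel pairs (i, j), i < j (the diagonal is excluded:
#' a "pair" of a channel with itself names no channel pair), finds the pair
#' with minimal and the pair with maximal [pair_distance()]. Ties go to the
#' first pair in row-major upper-triangle scan order. Each pair (a1, a2) is
#' encoded as the 0-based code `(a1 - 1) * nc + (a2 - 1)`.
#'
#' @param column Numeric vector of `nc >= 2` channel amplitudes.
#' @return Named numeric vector `c(val_min, val_max)` of codes in
#'   `[0, nc^2 - 1]`.
#' @export
#' @examples
#' encode_sample(c(3, 4, 0))  # val_min = 2 (pair 1,3), val_max = 1 (pair 1,2)
encode_sample <- function(column) {
  nc <- length(column)
  if (nc < 2L) stop("dimension error: need at least 2 channels", call. = FALSE)
  if (!all(is.finite(column))) {
    stop("value error: non-finite amplitudes", call. = FALSE)
  }
  pairs <- pair_index_table(nc)
  d2 <- column[pairs[, 1L]]^2 + column[pairs[, 2L]]^2  # sqrt is monotone
  i_min <- which.min(d2)
  i_max <- which.max(d2)
  c(val_min = encode_pair(pairs[i_min, 1L], pairs[i_min, 2L], nc),
    val_max = encode_pair(pairs[i_max, 1L], pairs[i_max, 2L], nc))
}

#' Decode a pair code back to its channel pair
#'
#' Exact inverse of the encoding in [encode_sample()]:
#' `a1 = floor(val / nc) + 1`, `a2 = (val mod nc) + 1`. The inverse is exact
#' on the encoder's image (codes with a1 < a2); other codes in
#' `[0, nc^2 - 1]` still decode arithmetically.
#'
#' @param val Integer code in `[0, nc^2 - 1]`.
#' @param nc Channel count.
#' @return Integer vector `c(a1, a2)` of 1-based channel indices.
#' @export
#' @examples
#' decode_code(1, 14)  # channels 1 and 2
decode_code <- function(val, nc) {
  if (any(val < 0 | val > nc^2 - 1)) {
    stop("value error: code out of range [0, nc^2 - 1]", call. = FALSE)
  }
  c(a1 = as.integer(val %/% nc) + 1L, a2 = as.integer(val %% nc) + 1L)
}

#' Encode every sample of a segment
#'
#' Applies [encode_sample()] to each of the L sample columns independently
#' (vectorized over the upper-triangle pair distances).
#'
#' @param segment An `eeg_segment` (from [segment_record()]) or a plain
#'   channels-by-samples numeric matrix.
#' @return Object of class `pair_code_sequence`: list with integer vectors
#'   `codes_min`, `codes_max` (length L, values in `[0, nc^2 - 1]`) and `nc`.
#' @export
encode_segment <- function(segment) {
  sig <- if (inherits(segment, "eeg_segment")) segment$signal else as.matrix(segment)
  nc <- nrow(sig)
  if (nc < 2L) stop("dimension error: need at least 2 channels", call. = FALSE)
  if (!all(is.finite(sig))) stop("value error: non-finite amplitudes", call. = FALSE)
  pairs <- pair_index_table(nc)
  s2 <- sig * sig
  d2 <- s2[pairs[, 1L], , drop = FALSE] + s2[pairs[, 2L], , drop = FALSE]
  ## first extremal pair per column, in scan order
  i_min <- max.col(-t(d2), ties.method = "first")
  i_max <- max.col(t(d2), ties.method = "first")
  structure(
    list(codes_min = encode_pair(pairs[i_min, 1L], pairs[i_min, 2L], nc),
         codes_max = encode_pair(pairs[i_max, 1L], pairs[i_max, 2L], nc),
         nc = nc),
    class = "pair_code_sequence"
  )
}

#' Histogram feature vectors of a pair-code sequence
#'
#' Bin counts of the min-distance and max-distance codes over the full code
#' range `0 .. nc^2 - 1`. Counts are raw (each vector sums to the number of
#' encoded samples); under the i < j pair convention only the
#' `nc (nc - 1) / 2` upper-triangle bins can be populated, but the vectors
#' keep the full `nc^2` length.
#'
#' @param codes A `pair_code_sequence` from [encode_segment()].
#' @return List with integer vectors `f1` (min-distance histogram) and `f2`
#'   (max-distance histogram), each of length `nc^2`, named `min_000` ... /
#'   `max_000` ...
#' @export
histogram_features <- function(codes) {
  stopifnot(inherits(codes, "pair_code_sequence"))
  nbin <- codes$nc^2
  f1 <- tabulate(codes$codes_min + 1L, nbins = nbin)
  f2 <- tabulate(codes$codes_max + 1L, nbins = nbin)
  fmt <- paste0("%0", max(3L, nchar(nbin - 1L)), "d")
  names(f1) <- sprintf(paste0("min_", fmt), 0:(nbin - 1L))
  names(f2) <- sprintf(paste0("max_", fmt), 0:(nbin - 1L))
  list(f1 = f1, f2 = f2)
}

#' Merge the min- and max-distance feature vectors
#'
#' Concatenates f1 and f2 into the merged vector f3 of length `2 * nc^2`.
#'
#' @param f1,f2 Equal-length feature vectors from [histogram_features()].
#' @return Numeric vector of length `2 * length(f1)`.
#' @export
merge_features <- function(f1, f2) {
  if (length(f1) != length(f2)) {
    stop("dimension error: f1 and f2 must have equal length", call. = FALSE)
  }
  c(f1, f2)
}

#' Extract the three DMPat feature matrices from a segment list
#'
#' Runs the full DMPat extractor on every segment: per-sample pair codes,
#' min/max histograms, and the merged vector. Row order matches segment
#' order.
#'
#' @param segments List of segments (from [segment_record()] /
#'   [segment_dataset()]) or of channels-by-samples matrices, all with the
#'   same channel count.
#' @return List of three matrices `f1`, `f2`, `f3` with `n_segments` rows
#'   and `nc^2`, `nc^2`, `2 * nc^2` columns.
#' @export
dmpat_features <- function(segments) {
  if (!length(segments)) stop("dimension error: no segments", call. = FALSE)
  per_seg <- lapply(segments, function(s) {
    h <- histogram_features(encode_segment(s))
    list(f1 = h$f1, f2 = h$f2)
  })
  p <- length(per_seg[[1]]$f1)
  if (!all(vapply(per_seg, function(h) length(h$f1) == p, logical(1)))) {
    stop("dimension error: segments have inconsistent channel counts", call. = FALSE)
  }
  f1 <- do.call(rbind, lapply(per_seg, `[[`, "f1"))
  f2 <- do.call(rbind, lapply(per_seg, `[[`, "f2"))
  list(f1 = f1, f2 = f2, f3 = cbind(f1, f2))
}
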