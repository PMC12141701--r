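#' Construct an EEG record
#'
#' A record is one full recording session: a channels-by-samples numeric
#' matrix with a class label, an identifier and a sampling rate. Channel rows
#' must match the montage order.
#'
#' @param signal Numeric matrix, `nc` channels x `S` samples.
#' @param fs Sampling rate in Hz.
#' @param label Class label (two-class problems downstream).
#' @param record_id Identifier of the recording session.
#' @param montage A [montage()]; the row count of `signal` must equal its
#'   channel count.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signal, fs, label, record_id, montage) {
  stopifnot(inherits(montage, "montage"))
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (nrow(signal) != montage$nc) {
    stop(sprintf("montage error: record has %d channels, montage expects %d",
                 nrow(signal), montage$nc), call. = FALSE)
  }
  if (nrow(signal) < 2L || ncol(signal) < 1L) {
    stop("dimension error: signal must be at least 2 channels x 1 sample",
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("value error: 'fs' must be a positive scalar", call. = FALSE)
  }
  if (!all(is.finite(signal))) {
    stop("value error: signal contains non-finite values", call. = FALSE)
  }
  rownames(signal) <- montage$channel_names
  structure(
    list(record_id = record_id, label = label, signal = signal, fs = fs,
         montage = montage),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> id=%s label=%s  %d ch x %d samples @ %g Hz\n",
              x$record_id, x$label, nrow(x$signal), ncol(x$signal), x$fs))
  invisible(x)
}

#' Split a record into fixed-length segments
#'
#' Cuts a record into consecutive non-overlapping windows of
#' `fs * window_seconds` samples (e.g. 1920 samples for 15 s at 128 Hz). A
#' trailing remainder shorter than one window is discarded. Each segment
#' inherits the record's label and id.
#'
#' @param record An [eeg_record()].
#' @param window_seconds Window length in seconds; `window_seconds * fs` must
#'   be a positive integer.
#' @return List of `eeg_segment` objects (possibly empty, with a warning, if
#'   the record is shorter than one window). Each segment is a list with
#'   `signal` (nc x L matrix), `label`, `parent_record_id` and
#'   `segment_index`.
#' @export
#' @examples
#' m <- default_montage()
#' rec <- eeg_record(matrix(rnorm(14 * 3840), 14), fs = 128,
#'                   label = 1, record_id = "r1", montage = m)
#' length(segment_record(rec, 15))  # 2 segments of 1920 samples
segment_record <- function(record, window_seconds = 15) {
  stopifnot(inherits(record, "eeg_record"))
  L <- record$fs * window_seconds
  if (L <= 0 || abs(L - round(L)) > 1e-9) {
    stop("value error: window_seconds * fs must be a positive integer",
         call. = FALSE)
  }
  L <- as.integer(round(L))
  S <- ncol(record$signal)
  n_seg <- S %/% L
  if (n_seg == 0L) {
    warning(sprintf("record '%s' (%d samples) is shorter than one window (%d); no segments",
                    record$record_id, S, L))
    return(list())
  }
  lapply(seq_len(n_seg), function(i) {
    structure(
      list(signal = record$signal[, ((i - 1L) * L + 1L):(i * L), drop = FALSE],
           label = record$label,
           parent_record_id = record$record_id,
           segment_index = i),
      class = "eeg_segment"
    )
  })
}

#' Segment every record of a dataset
#'
#' @param records List of [eeg_record()] objects.
#' @param window_seconds Window length in seconds (default 15).
#' @return List with `segments` (flat list of segments), `labels`, and
#'   `record_ids` (one entry per segment, in segment order).
#' @export
segment_dataset <- function(records, window_seconds = 15) {
  segs <- unlist(lapply(records, segment_record, window_seconds = window_seconds),
                 recursive = FALSE)
  list(
    segments = segs,
    labels = vapply(segs, function(s) s$label, FUN.VALUE = vector(mode = typeof(records[[1]]$label), 1L)),
    record_ids = vapply(segs, function(s) as.character(s$parent_record_id), character(1))
  )
}
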