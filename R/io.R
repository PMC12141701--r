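## Readers for the three supported on-disk signal layouts: delimited text,
## EDF, and MATLAB v7.3 (HDF5) containers. No filtering, re-referencing or
## artifact handling is done here: signals are read verbatim.

#' Load one EEG record from disk
#'
#' Reads a multichannel signal matrix and validates it against a montage.
#' Supported formats:
#' \describe{
#'   \item{`delimited`}{CSV/TSV numeric matrix, channels in rows by default
#'     (see `orientation`). A header line of channel names, when present, is
#'     used to reorder channels to montage order; otherwise channels are
#'     taken positionally.}
#'   \item{`edf`}{European Data Format; channel labels from the EDF signal
#'     headers are matched (case-insensitively) against the montage and rows
#'     are reordered to montage order. The sampling rate is taken from the
#'     file.}
#'   \item{`matlab`}{MATLAB v7.3 container (HDF5-based), read through the
#'     \pkg{rhdf5} package. The variable is selected by `var`, defaulting to
#'     the first 2-D numeric dataset. Classic (v5) MAT files are not
#'     supported and raise an error suggesting a v7.3 re-save or CSV export.}
#' }
#'
#' @param path File path.
#' @param montage A [montage()].
#' @param label Class label to attach.
#' @param record_id Record identifier; defaults to the file name.
#' @param format One of `"auto"`, `"delimited"`, `"edf"`, `"matlab"`.
#'   `"auto"` dispatches on the file extension (.edf, .mat, else delimited).
#' @param fs Sampling rate in Hz; required for delimited and MATLAB input,
#'   ignored for EDF (the file carries it).
#' @param orientation For delimited/MATLAB matrices: `"channels_in_rows"`
#'   (default) or `"channels_in_columns"`.
#' @param var For MATLAB containers: name of the variable to read
#'   (default: first 2-D numeric dataset).
#' @return An [eeg_record()].
#' @export
load_record <- function(path, montage, label, record_id = basename(path),
                        format = c("auto", "delimited", "edf", "matlab"),
                        fs = NULL,
                        orientation = c("channels_in_rows", "channels_in_columns"),
                        var = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("format error: file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", mat = "matlab", "delimited")
  }
  if (format == "edf") {
    edf <- read_edf(path)
    sig <- reorder_channels(edf$signal, edf$channel_names, montage)
    return(eeg_record(sig, fs = edf$fs, label = label, record_id = record_id,
                      montage = montage))
  }
  if (is.null(fs)) {
    stop("value error: 'fs' is required for ", format, " input", call. = FALSE)
  }
  mat <- switch(format,
    delimited = read_delimited_matrix(path),
    matlab = list(signal = read_mat73_matrix(path, var = var), channel_names = NULL)
  )
  sig <- mat$signal
  if (orientation == "channels_in_columns") {
    sig <- t(sig)
    mat$channel_names <- mat$col_names
  }
  sig <- reorder_channels(sig, mat$channel_names, montage)
  eeg_record(sig, fs = fs, label = label, record_id = record_id,
             montage = montage)
}

## Match rows to montage order. With names: exact case-insensitive match of
## the full channel set. Without names: positional, count must agree.
reorder_channels <- function(signal, channel_names, montage) {
  if (nrow(signal) != montage$nc) {
    stop(sprintf("montage error: file has %d channels, montage expects %d",
                 nrow(signal), montage$nc), call. = FALSE)
  }
  if (is.null(channel_names)) {
    return(signal)
  }
  idx <- match(toupper(montage$channel_names), toupper(trimws(channel_names)))
  if (anyNA(idx)) {
    stop("montage error: channel names in file do not cover the montage: missing ",
         paste(montage$channel_names[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  signal[idx, , drop = FALSE]
}

read_delimited_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("format error: empty file: ", path, call. = FALSE)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tokens <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(tokens)))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          check.names = FALSE, comment.char = "")
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    stop("format error: non-numeric values in ", path, call. = FALSE)
  }
  dimnames(mat) <- NULL
  ## a header names columns; it names channels only in channels-in-columns
  ## layout, which load_record() resolves via 'orientation'
  list(signal = mat, channel_names = NULL,
       col_names = if (has_header) colnames(df) else NULL)
}

## ---- EDF ------------------------------------------------------------------

## Minimal EDF reader: fixed-width ASCII header + per-record interleaved
## little-endian int16 samples, rescaled to physical units. Annotation
## channels are dropped. All retained channels must share one sampling rate.

#' Read a European Data Format (EDF) file
#'
#' @param path Path to the .edf file.
#' @return List with `signal` (channels x samples matrix, physical units),
#'   `channel_names`, and `fs` (Hz).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_chr <- function(n) rawToChar(readBin(con, "raw", n))
  hdr_num <- function(n) suppressWarnings(as.numeric(trimws(hdr_chr(n))))
  version <- trimws(hdr_chr(8))
  if (version != "0") {
    stop("format error: not an EDF file (version field '", version, "')",
         call. = FALSE)
  }
  hdr_chr(80 + 80 + 8 + 8)              # patient, recording, date, time
  hdr_num(8)                            # header byte count (recomputed below)
  hdr_chr(44)
  n_records <- hdr_num(8)
  duration <- hdr_num(8)
  ns <- as.integer(hdr_num(4))
  if (is.na(ns) || ns < 1L) stop("format error: bad EDF signal count", call. = FALSE)
  field <- function(width, fun = trimws) {
    vapply(seq_len(ns), function(i) fun(rawToChar(readBin(con, "raw", width))),
           character(1))
  }
  labels <- field(16)
  field(80); field(8)                   # transducer, physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                             # prefiltering
  spr <- as.integer(field(8))           # samples per data record, per signal
  field(32)
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (!any(keep)) stop("format error: EDF file holds only annotations", call. = FALSE)
  if (length(unique(spr[keep])) != 1L) {
    stop("format error: EDF signals have unequal sampling rates", call. = FALSE)
  }
  if (is.na(n_records) || n_records < 1L) {
    stop("format error: EDF file declares no data records", call. = FALSE)
  }
  sig <- matrix(0, nrow = sum(keep), ncol = n_records * spr[keep][1])
  col0 <- 0L
  for (r in seq_len(n_records)) {
    pos <- 0L
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2L,
                     signed = TRUE, endian = "little")
      if (length(raw) < spr[s]) stop("format error: truncated EDF file", call. = FALSE)
      if (keep[s]) {
        pos <- pos + 1L
        gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
        sig[pos, (col0 + 1L):(col0 + spr[s])] <-
          (raw - dig_min[s]) * gain + phys_min[s]
      }
    }
    col0 <- col0 + spr[keep][1]
  }
  list(signal = sig, channel_names = labels[keep],
       fs = spr[keep][1] / duration)
}

## Minimal EDF writer (internal; used for reader round-trip tests and for
## exporting synthetic data). One data record per second.
write_edf <- function(signal, channel_names, fs, path) {
  stopifnot(nrow(signal) == length(channel_names), fs == as.integer(fs))
  ns <- nrow(signal)
  n_records <- ncol(signal) %/% fs
  if (n_records < 1L) stop("value error: signal shorter than one EDF record", call. = FALSE)
  signal <- signal[, seq_len(n_records * fs), drop = FALSE]
  phys_min <- floor(min(signal)); phys_max <- ceiling(max(signal))
  if (phys_max <= phys_min) phys_max <- phys_min + 1
  dig_min <- -32768; dig_max <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(paste0(vapply(x, pad, "", w = w),
                                                 collapse = "")), con)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(n_records, 8); wr("1", 8); wr(ns, 4)
  wr(channel_names, 16); wr(rep("", ns), 80); wr(rep("uV", ns), 8)
  wr(rep(phys_min, ns), 8); wr(rep(phys_max, ns), 8)
  wr(rep(dig_min, ns), 8); wr(rep(dig_max, ns), 8)
  wr(rep("", ns), 80); wr(rep(fs, ns), 8); wr(rep("", ns), 32)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- round((signal - phys_min) * gain + dig_min)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[s, cols]), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

## ---- MATLAB v7.3 ----------------------------------------------------------

read_mat73_matrix <- function(path, var = NULL) {
  magic <- readBin(path, "raw", 8L)
  if (length(magic) >= 8 && rawToChar(magic[1:6]) == "MATLAB") {
    stop("format error: classic MATLAB v5 .mat files are not supported; ",
         "re-save with '-v7.3' or export to CSV", call. = FALSE)
  }
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("format error: reading MATLAB v7.3 containers requires the 'rhdf5' package",
         call. = FALSE)
  }
  info <- rhdf5::h5ls(path)
  dsets <- info[info$otype == "H5I_DATASET", , drop = FALSE]
  pick <- if (!is.null(var)) {
    i <- which(dsets$name == var)
    if (!length(i)) stop("format error: variable '", var, "' not found in ", path,
                         call. = FALSE)
    i[1]
  } else {
    i <- which(vapply(strsplit(dsets$dim, " x "), length, 0L) == 2L)
    if (!length(i)) stop("format error: no 2-D dataset in ", path, call. = FALSE)
    i[1]
  }
  obj <- paste0(sub("/$", "", dsets$group[pick]), "/", dsets$name[pick])
  x <- rhdf5::h5read(path, obj)
  if (!is.numeric(x) || length(dim(x)) != 2L) {
    stop("format error: dataset '", obj, "' is not a 2-D numeric matrix",
         call. = FALSE)
  }
  ## MATLAB v7.3 stores arrays with dimensions reversed; transpose back
  t(as.matrix(x))
}

## ---- dataset manifests ----------------------------------------------------

#' Load a dataset described by a manifest table
#'
#' The manifest is a delimited table with columns `path`, `record_id` and
#' `label`. Relative paths are resolved against the manifest's directory.
#'
#' @param manifest_path Path to the manifest (TSV or CSV).
#' @param montage A [montage()].
#' @param fs Sampling rate for delimited/MATLAB files.
#' @param ... Further arguments passed to [load_record()] (e.g.
#'   `orientation`).
#' @return List of [eeg_record()] objects.
#' @export
load_dataset <- function(manifest_path, montage, fs = NULL, ...) {
  if (!file.exists(manifest_path)) {
    stop("format error: manifest not found: ", manifest_path, call. = FALSE)
  }
  first <- readLines(manifest_path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  man <- utils::read.table(manifest_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("path", "record_id", "label")
  if (!all(need %in% names(man))) {
    stop("format error: manifest must have columns path, record_id, label",
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    load_record(p, montage = montage, label = man$label[i],
                record_id = as.character(man$record_id[i]), fs = fs, ...)
  })
}

## ---- feature matrix I/O ---------------------------------------------------

#' Write / read a feature matrix as a delimited table
#'
#' Features are written as tab-separated text with a header row naming the
#' histogram bins (`min_000` ... `min_195`, `max_000` ..., in 0-based code
#' order).
#'
#' @param features Numeric matrix (segments x features) with column names.
#' @param path Output path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the matrix.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}
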