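#' @keywords internal
"_PACKAGE"

## The eight Directed Lobish symbols: frontal/occipital/parietal/temporal,
## left/right. Fixed order used for histograms and transition matrices.
DLOB_SYMBOLS <- c("FL", "FR", "OL", "OR", "PL", "PR", "TL", "TR")

#' Construct an EEG montage
#'
#' A montage pairs an ordered set of channel labels with the brain-lobe
#' symbol each channel projects to under the Directed Lobish (DLob) symbolic
#' language. The lobe symbols are `FL`/`FR` (frontal left/right), `OL`/`OR`
#' (occipital), `PL`/`PR` (parietal) and `TL`/`TR` (temporal).
#'
#' @param channel_names Character vector of channel labels, in acquisition
#'   order.
#' @param lobe_symbols Character vector of the same length; each entry one of
#'   `FL, FR, OL, OR, PL, PR, TL, TR`.
#' @return An object of class `montage`: a list with elements
#'   `channel_names`, `lobe_symbols` and `nc` (channel count).
#' @seealso [default_montage()], [lobe_table()]
#' @export
#' @examples
#' m <- montage(c("C3", "C4"), c("PL", "PR"))
#' m$nc
montage <- function(channel_names, lobe_symbols) {
  channel_names <- as.character(channel_names)
  lobe_symbols <- as.character(lobe_symbols)
  if (length(channel_names) != length(lobe_symbols)) {
    stop("montage error: 'channel_names' and 'lobe_symbols' must have equal length",
         call. = FALSE)
  }
  if (length(channel_names) < 2L) {
    stop("montage error: a montage needs at least 2 channels", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("montage error: duplicated channel names", call. = FALSE)
  }
  bad <- setdiff(unique(lobe_symbols), DLOB_SYMBOLS)
  if (length(bad)) {
    stop("montage error: unknown lobe symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(channel_names = channel_names, lobe_symbols = lobe_symbols,
         nc = length(channel_names)),
    class = "montage"
  )
}

#' The 14-channel consumer headset montage
#'
#' The standard 14-channel montage (AF3, F7, F3, FC5, T7, P7, O1, O2, P8,
#' T8, FC6, F4, F8, AF4 at 128 Hz on the Epoc-family headset) together with
#' its channel-to-lobe lookup: the first four channels are left frontal, the
#' last four right frontal, with temporal, parietal and occipital electrodes
#' in between.
#'
#' @return A [montage()] with 14 channels.
#' @export
#' @examples
#' default_montage()$lobe_symbols
default_montage <- function() {
  montage(
    channel_names = c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                      "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"),
    lobe_symbols = c("FL", "FL", "FL", "FL", "TL", "PL", "OL",
                     "OR", "PR", "TR", "FR", "FR", "FR", "FR")
  )
}

#' Channel-to-lobe lookup table of a montage
#'
#' @param montage A [montage()].
#' @return Named character vector: one DLob symbol per channel, named by
#'   channel label.
#' @export
#' @examples
#' lobe_table(default_montage())[["T7"]]
lobe_table <- function(montage) {
  stopifnot(inherits(montage, "montage"))
  stats::setNames(montage$lobe_symbols, montage$channel_names)
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels\n", x$nc))
  cat(paste(sprintf("%s(%s)", x$channel_names, x$lobe_symbols), collapse = " "),
      "\n")
  invisible(x)
}
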