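## Directed Lobish (DLob) explainability: selected DMPat feature indices are
## decoded back to their channel pairs, each channel is mapped to its brain
## lobe symbol, and the resulting symbol strings are summarized by
## histograms, Shannon entropy and transition (connectome) matrices.

#' Map a selected feature index to its channel pair
#'
#' A DMPat feature index (1-based) addresses one histogram bin, i.e. one
#' pair code. For merged vectors of length `2 * nc^2`, indices above `nc^2`
#' live in the max-distance code space and are reduced by `nc^2` first. The
#' underlying 0-based code `val = index - 1` is then decoded as
#' `ch1 = floor(val / nc) + 1`, `ch2 = (val mod nc) + 1` — the exact inverse
#' of the DMPat encoding.
#'
#' @param index 1-based feature index.
#' @param nc Channel count.
#' @param source_kind `"min_distance"`, `"max_distance"` or `"merged"`.
#' @return Integer vector `c(ch1, ch2)` of 1-based channel indices.
#' @export
#' @examples
#' feature_index_to_channels(2, 14)                      # channels 1, 2
#' feature_index_to_channels(198, 14, "merged")          # also 1, 2
feature_index_to_channels <- function(index, nc,
                                      source_kind = c("min_distance",
                                                      "max_distance",
                                                      "merged")) {
  source_kind <- match.arg(source_kind)
  max_len <- if (source_kind == "merged") 2L * nc^2 else nc^2
  if (index < 1L || index > max_len) {
    stop("value error: feature index out of range for ", source_kind,
         " vector", call. = FALSE)
  }
  if (source_kind == "merged" && index > nc^2) index <- index - nc^2
  unname(decode_code(index - 1L, nc))
}

#' Build a DLob string from selected feature indices
#'
#' For each selected feature in order, both decoded channels are passed
#' through the montage's channel-to-lobe lookup and appended, giving two
#' symbols per feature (string length 2N).
#'
#' @param chosen_indices Integer vector of 1-based feature indices (e.g.
#'   `chosen_indices` of a [inca_select()] result).
#' @param montage A [montage()].
#' @param source_kind Feature space of the indices; see
#'   [feature_index_to_channels()].
#' @return Object of class `dlob_string`: character vector of lobe symbols
#'   with attribute `source_kind`.
#' @export
build_dlob_string <- function(chosen_indices, montage,
                              source_kind = c("min_distance", "max_distance",
                                              "merged")) {
  source_kind <- match.arg(source_kind)
  tab <- lobe_table(montage)
  symbols <- unlist(lapply(chosen_indices, function(i) {
    ch <- feature_index_to_channels(i, montage$nc, source_kind)
    unname(tab[ch])
  }))
  if (is.null(symbols)) symbols <- character(0)
  structure(symbols, source_kind = source_kind, class = "dlob_string")
}

#' @export
print.dlob_string <- function(x, ...) {
  cat(sprintf("<dlob_string> %d symbols (%s)\n", length(x),
              attr(x, "source_kind")))
  cat(paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

#' Symbol histogram of a DLob string
#'
#' @param dls A `dlob_string` or plain character vector of DLob symbols.
#' @return Named integer vector of counts over the eight symbols
#'   (FL, FR, OL, OR, PL, PR, TL, TR); sums to the string length.
#' @export
symbol_histogram <- function(dls) {
  dls <- as.character(dls)
  bad <- setdiff(unique(dls), DLOB_SYMBOLS)
  if (length(bad)) {
    stop("value error: unknown DLob symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(factor(dls, levels = DLOB_SYMBOLS))
  stats::setNames(as.integer(tab), DLOB_SYMBOLS)
}

#' Shannon entropy of a DLob string
#'
#' `-sum(p_s * log(p_s))` over the observed symbol frequencies; zero-count
#' symbols contribute nothing. Base 2 (bits) by default.
#'
#' @param dls A `dlob_string` or character vector of DLob symbols
#'   (non-empty).
#' @param base `2` (bits, default) or `exp(1)` (nats).
#' @return Non-negative entropy value.
#' @export
#' @examples
#' shannon_entropy(c("FL", "FR"))  # 1 bit
shannon_entropy <- function(dls, base = 2) {
  dls <- as.character(dls)
  if (!length(dls)) stop("value error: empty DLob string", call. = FALSE)
  p <- symbol_histogram(dls) / length(dls)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Transition matrix of a DLob string
#'
#' Counts symbol-to-symbol transitions into an 8 x 8 matrix (rows = from,
#' columns = to), the weighted adjacency of the cortical connectome graph.
#' Two modes:
#' \describe{
#'   \item{`consecutive`}{all adjacent positions c -> c + 1; total count =
#'     length - 1.}
#'   \item{`per_feature_pair`}{only within-feature pairs (positions 1 -> 2,
#'     3 -> 4, ...); total count = length / 2.}
#' }
#'
#' @param dls A `dlob_string` or character vector (length >= 2; even length
#'   for `per_feature_pair`).
#' @param mode `"consecutive"` (default) or `"per_feature_pair"`.
#' @return Object of class `connectome_matrix`: 8 x 8 integer matrix with
#'   dimnames over the DLob symbols and attribute `mode`.
#' @export
transition_matrix <- function(dls, mode = c("consecutive", "per_feature_pair")) {
  mode <- match.arg(mode)
  dls <- as.character(dls)
  if (length(dls) < 2L) {
    stop("value error: need at least 2 symbols for transitions", call. = FALSE)
  }
  if (mode == "per_feature_pair" && length(dls) %% 2L != 0L) {
    stop("value error: per_feature_pair mode needs an even-length string",
         call. = FALSE)
  }
  from_idx <- if (mode == "consecutive") seq_len(length(dls) - 1L)
              else seq(1L, length(dls) - 1L, by = 2L)
  from <- factor(dls[from_idx], levels = DLOB_SYMBOLS)
  to <- factor(dls[from_idx + 1L], levels = DLOB_SYMBOLS)
  if (anyNA(from) || anyNA(to)) {
    stop("value error: unknown DLob symbol in string", call. = FALSE)
  }
  counts <- table(from, to)
  m <- matrix(as.integer(counts), 8L, 8L,
              dimnames = list(from = DLOB_SYMBOLS, to = DLOB_SYMBOLS))
  structure(m, mode = mode, class = c("connectome_matrix", "matrix"))
}

#' Export a connectome matrix as a directed weighted graph
#'
#' Writes the transition counts as a directed graph over the eight lobe
#' symbols (edge weight = count, zero-count edges omitted) in DOT or GraphML
#' (via \pkg{igraph}) or as a JSON edge list.
#'
#' @param cm A `connectome_matrix` from [transition_matrix()].
#' @param path Output file path.
#' @param format `"dot"`, `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_connectome <- function(cm, path, format = c("dot", "graphml", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(cm, "connectome_matrix"))
  m <- unclass(cm)
  attr(m, "mode") <- NULL
  if (format == "json") {
    idx <- which(m > 0, arr.ind = TRUE)
    edges <- data.frame(from = rownames(m)[idx[, 1]],
                        to = colnames(m)[idx[, 2]],
                        weight = m[idx])
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    jsonlite::write_json(
      list(nodes = DLOB_SYMBOLS, mode = attr(cm, "mode"), edges = edges),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    g <- igraph::graph_from_adjacency_matrix(m, mode = "directed",
                                             weighted = TRUE)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Full DLob report for one selection result
#'
#' Bundles the string, histogram, entropy and transition matrix for a
#' branch's selected features.
#'
#' @param selection A [inca_select()] result (or a vector of indices).
#' @param montage A [montage()].
#' @param source_kind Feature space of the indices.
#' @param entropy_base Entropy base (default 2).
#' @param transition_mode Passed to [transition_matrix()].
#' @return List with `string`, `histogram`, `entropy`, `entropy_base`,
#'   `transitions`, `source_kind`.
#' @export
dlob_report <- function(selection, montage,
                        source_kind = c("min_distance", "max_distance",
                                        "merged"),
                        entropy_base = 2,
                        transition_mode = "consecutive") {
  source_kind <- match.arg(source_kind)
  idx <- if (inherits(selection, "selection_result")) selection$chosen_indices
         else as.integer(selection)
  dls <- build_dlob_string(idx, montage, source_kind)
  list(string = dls,
       histogram = symbol_histogram(dls),
       entropy = shannon_entropy(dls, base = entropy_base),
       entropy_base = entropy_base,
       transitions = transition_matrix(dls, transition_mode),
       source_kind = source_kind)
}
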