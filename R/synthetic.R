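## Synthetic two-class EEG generator. The class signal is amplitude
## structure, not oscillatory content: each channel is AR(1)-correlated
## Gaussian noise scaled by a class-specific gain profile. Because the DMPat
## encoder reacts to instantaneous amplitudes, suppressing a different
## channel pair in each class plants a separable min-distance code
## structure.

#' Synthetic dataset configuration
#'
#' Defaults emulate the structure of a two-class 14-channel 128 Hz consumer
#' headset study: records split into 15-s segments, ~8 segments per record,
#' and a planted class contrast in which class 1 damps channels 1-2 and
#' class 2 damps channels 7-8 by a factor of 10.
#'
#' @param nc Channel count (default 14).
#' @param fs Sampling rate in Hz (default 128).
#' @param window_seconds Segment length in seconds (default 15).
#' @param records_per_class Records per class (default 10).
#' @param segments_per_record Whole segments per record (default 8).
#' @param class_gain_profiles List of two positive numeric vectors of length
#'   `nc`: per-channel amplitude multipliers for class 1 and class 2.
#'   Identical profiles give an unlearnable null dataset.
#' @param noise_sd Innovation standard deviation (default 1).
#' @param ar_coefficient AR(1) coefficient in `[0, 1)` (default 0.9, the
#'   strong short-lag autocorrelation typical of low-pass EEG).
#' @param seed Integer seed.
#' @return Object of class `synth_config` (a validated list).
#' @export
synth_config <- function(nc = 14L, fs = 128L, window_seconds = 15,
                         records_per_class = 10L, segments_per_record = 8L,
                         class_gain_profiles = NULL, noise_sd = 1,
                         ar_coefficient = 0.9, seed = 1L) {
  if (nc < 2L || fs <= 0 || window_seconds <= 0 || records_per_class < 1L ||
      segments_per_record < 1L || noise_sd <= 0 ||
      ar_coefficient < 0 || ar_coefficient >= 1) {
    stop("value error: degenerate synthetic configuration", call. = FALSE)
  }
  if (is.null(class_gain_profiles)) {
    g1 <- rep(1, nc); g1[c(1L, 2L)] <- 0.1
    g2 <- rep(1, nc); g2[c(min(7L, nc - 1L), min(8L, nc))] <- 0.1
    class_gain_profiles <- list(g1, g2)
  }
  if (length(class_gain_profiles) != 2L ||
      !all(vapply(class_gain_profiles, length, 0L) == nc) ||
      !all(unlist(class_gain_profiles) > 0)) {
    stop("value error: class_gain_profiles must be two positive length-nc vectors",
         call. = FALSE)
  }
  structure(
    list(nc = as.integer(nc), fs = as.integer(fs),
         window_seconds = window_seconds,
         records_per_class = as.integer(records_per_class),
         segments_per_record = as.integer(segments_per_record),
         class_gain_profiles = class_gain_profiles,
         noise_sd = noise_sd, ar_coefficient = ar_coefficient,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic two-class EEG dataset
#'
#' Each record is `segments_per_record * window_seconds` seconds of
#' channelwise AR(1) Gaussian noise scaled by the class gain profile.
#' Labels are 1 and 2, balanced; record ids are unique; the same seed
#' reproduces the dataset exactly.
#'
#' @param cfg A [synth_config()].
#' @param montage Optional [montage()] with `cfg$nc` channels; a generic one
#'   (all-left-frontal except mirrored right half) is built when the default
#'   14-channel montage does not fit.
#' @return List of [eeg_record()] objects (class 1 records first).
#' @export
generate_dataset <- function(cfg = synth_config(), montage = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(montage)) {
    montage <- if (cfg$nc == 14L) default_montage() else generic_montage(cfg$nc)
  }
  if (montage$nc != cfg$nc) {
    stop("montage error: montage size does not match cfg$nc", call. = FALSE)
  }
  S <- as.integer(round(cfg$fs * cfg$window_seconds)) * cfg$segments_per_record
  phi <- cfg$ar_coefficient
  ## stationary AR(1): innovations scaled so the marginal sd is noise_sd
  innov_sd <- cfg$noise_sd * sqrt(1 - phi^2)
  records <- with_seed(cfg$seed, {
    out <- vector("list", 2L * cfg$records_per_class)
    r <- 0L
    for (cl in 1:2) {
      gains <- cfg$class_gain_profiles[[cl]]
      for (i in seq_len(cfg$records_per_class)) {
        r <- r + 1L
        sig <- matrix(0, cfg$nc, S)
        for (ch in seq_len(cfg$nc)) {
          e <- stats::rnorm(S, sd = innov_sd)
          x <- stats::filter(e, phi, method = "recursive",
                             init = stats::rnorm(1, sd = cfg$noise_sd))
          sig[ch, ] <- as.numeric(x) * gains[ch]
        }
        out[[r]] <- eeg_record(sig, fs = cfg$fs, label = cl,
                               record_id = sprintf("c%d_r%02d", cl, i),
                               montage = montage)
      }
    }
    out
  })
  records
}

## placeholder montage for non-14-channel synthetic data: splits channels
## into left/right frontal halves (lobe identity is irrelevant to the
## classifier; only the explainability layer reads it)
generic_montage <- function(nc) {
  half <- nc %/% 2L
  montage(channel_names = sprintf("CH%02d", seq_len(nc)),
          lobe_symbols = c(rep("FL", half), rep("FR", nc - half)))
}

#' Write a dataset to disk as delimited files plus a manifest
#'
#' One CSV per record (channels in rows) and a tab-separated manifest with
#' columns `path`, `record_id`, `label`, consumable by [load_dataset()].
#'
#' @param records List of [eeg_record()] objects.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest file, invisibly.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(rec) {
    fname <- paste0(rec$record_id, ".csv")
    utils::write.table(rec$signal, file.path(dir, fname), sep = ",",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    data.frame(path = fname, record_id = rec$record_id, label = rec$label)
  })
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(man_path)
}
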