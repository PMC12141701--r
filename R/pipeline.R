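## End-to-end pipeline: segmentation -> DMPat -> INCA (per branch) -> tkNN
## (per branch, shared outer partition) -> mode fusion -> greedy final
## outcome -> metrics + DLob reports.

#' Pipeline run configuration
#'
#' @param window_seconds Segment length in seconds (default 15).
#' @param cv_scheme `"loro"` (leave-one-record-out, default) or
#'   `"tenfold"`.
#' @param n_folds Folds for the tenfold scheme.
#' @param inca_start,inca_stop Subset-size range of the iterative selector
#'   (defaults 14 and 98).
#' @param positive_class Label treated as positive in the metrics
#'   (default 1, the "violence" class of the two-class design).
#' @param entropy_base Base of the DLob string entropy (default 2).
#' @param transition_mode Connectome transition mode; see
#'   [transition_matrix()].
#' @param seed Integer master seed; sub-seeds for the selector CV and the
#'   outer partition are derived from it deterministically.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(window_seconds = 15, cv_scheme = c("loro", "tenfold"),
                       n_folds = 10L, inca_start = 14L, inca_stop = 98L,
                       positive_class = 1, entropy_base = 2,
                       transition_mode = "consecutive", seed = 1L) {
  cv_scheme <- match.arg(cv_scheme)
  structure(
    list(window_seconds = window_seconds, cv_scheme = cv_scheme,
         n_folds = as.integer(n_folds),
         inca_start = as.integer(inca_start),
         inca_stop = as.integer(inca_stop),
         positive_class = positive_class, entropy_base = entropy_base,
         transition_mode = transition_mode, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full SOXFE pipeline
#'
#' Segments every record, extracts the three DMPat feature matrices
#' (min-distance, max-distance, merged), runs the iterative NCA selector
#' and the tkNN ensemble on each branch (all branches share one outer CV
#' partition so the fused predictions are aligned), fuses the three branch
#' outcomes by the mode operator, greedily keeps the best of the four, and
#' reports metrics plus the DLob explainability summaries.
#'
#' Feature selection sees the full dataset before the outer validation
#' split, matching the method's published protocol (selection is not nested
#' inside the outer folds).
#'
#' @param records List of [eeg_record()] objects.
#' @param config A [run_config()].
#' @return Object of class `soxfe_report`: list with elements `config`,
#'   `n_segments`, `labels`, `record_ids`, `partition`, `branches` (per
#'   branch: `selection`, `outcomes`, `metrics`, `dlob`), `vot`, `fot`,
#'   `metrics` (named list: t1, t2, t3, vot, fot).
#' @export
run_pipeline <- function(records, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!length(records)) stop("value error: empty dataset", call. = FALSE)
  montage <- records[[1]]$montage

  ds <- segment_dataset(records, config$window_seconds)
  labels <- ds$labels
  if (length(unique(labels)) != 2L) {
    stop("degenerate-label error: pipeline expects a two-class dataset",
         call. = FALSE)
  }
  feats <- dmpat_features(ds$segments)

  partition <- make_partition(labels, record_ids = ds$record_ids,
                              scheme = config$cv_scheme,
                              seed = derive_seed(config$seed, 1L),
                              n_folds = config$n_folds)

  kinds <- c("min_distance", "max_distance", "merged")
  branches <- vector("list", 3L)
  names(branches) <- c("f1", "f2", "f3")
  for (h in 1:3) {
    f <- feats[[h]]
    sel <- inca_select(f, labels, start = config$inca_start,
                       stop = min(config$inca_stop, ncol(f)),
                       seed = derive_seed(config$seed, 2L))
    out <- tknn(f[, sel$chosen_indices, drop = FALSE], labels,
                partition$fold_of)
    branches[[h]] <- list(
      selection = sel,
      outcomes = out,
      metrics = compute_metrics(out$best_predictions, labels,
                                config$positive_class),
      dlob = dlob_report(sel, montage, source_kind = kinds[h],
                         entropy_base = config$entropy_base,
                         transition_mode = config$transition_mode)
    )
  }

  t1 <- branches$f1$outcomes$best_predictions
  t2 <- branches$f2$outcomes$best_predictions
  t3 <- branches$f3$outcomes$best_predictions
  vot <- fuse_mode(t1, t2, t3)
  fot <- greedy_final(t1, t2, t3, vot, labels)

  metrics <- list(
    t1 = branches$f1$metrics,
    t2 = branches$f2$metrics,
    t3 = branches$f3$metrics,
    vot = compute_metrics(vot, labels, config$positive_class),
    fot = compute_metrics(fot$predictions, labels, config$positive_class)
  )

  structure(
    list(config = config,
         n_segments = length(labels),
         labels = labels,
         record_ids = ds$record_ids,
         partition = partition,
         branches = branches,
         vot = vot,
         fot = fot,
         metrics = metrics),
    class = "soxfe_report"
  )
}

## sub-seed derivation; keeps results independent across uses of the master
## seed while staying inside the 32-bit integer range
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + stream * 12289L) %% .Machine$integer.max)
}

#' @export
print.soxfe_report <- function(x, ...) {
  cat(sprintf("<soxfe_report> %d segments, %s CV (%d folds)\n",
              x$n_segments, x$partition$scheme, x$partition$n_folds))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-3s acc %6.2f  sen %6.2f  spe %6.2f  gm %6.2f\n",
                nm, m$accuracy, m$sensitivity, m$specificity,
                m$geometric_mean))
  }
  cat(sprintf("  final outcome: %s (selected sizes %d/%d/%d; DLob lengths %d/%d/%d)\n",
              x$fot$which,
              x$branches$f1$selection$n_selected,
              x$branches$f2$selection$n_selected,
              x$branches$f3$selection$n_selected,
              length(x$branches$f1$dlob$string),
              length(x$branches$f2$dlob$string),
              length(x$branches$f3$dlob$string)))
  invisible(x)
}

#' Serialize a pipeline report to JSON and per-segment predictions to TSV
#'
#' Writes `report.json` (config, selections, loss curves, accuracies, DLob
#' summaries, metrics — no timestamps, so identical runs produce identical
#' bytes), `predictions.tsv` (segment id, record id, truth, t1..t3, vot,
#' fot) and one connectome graph file per branch.
#'
#' @param report A `soxfe_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @param connectome_format `"dot"`, `"graphml"` or `"json"`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, connectome_format = "json") {
  stopifnot(inherits(report, "soxfe_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_as_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  preds <- data.frame(
    segment = seq_len(report$n_segments),
    record_id = report$record_ids,
    truth = report$labels,
    t1 = report$branches$f1$outcomes$best_predictions,
    t2 = report$branches$f2$outcomes$best_predictions,
    t3 = report$branches$f3$outcomes$best_predictions,
    vot = report$vot,
    fot = report$fot$predictions
  )
  utils::write.table(preds, file.path(dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(report$branches)) {
    export_connectome(report$branches[[nm]]$dlob$transitions,
                      file.path(dir, paste0("connectome_", nm, ".",
                                            connectome_format)),
                      format = connectome_format)
  }
  invisible(dir)
}

report_as_list <- function(report) {
  branch_list <- lapply(report$branches, function(b) {
    list(
      selection = list(
        chosen_r = b$selection$chosen_r,
        chosen_indices = b$selection$chosen_indices,
        ranked_indices = b$selection$ranked_indices,
        loss_curve = as.numeric(b$selection$loss_curve),
        start = b$selection$start, stop = b$selection$stop,
        seed = b$selection$seed
      ),
      outcomes = list(
        accuracies = as.numeric(b$outcomes$accuracies),
        best_index = b$outcomes$best_index,
        best_accuracy = b$outcomes$best_accuracy
      ),
      metrics = unclass(b$metrics),
      dlob = list(
        string = as.character(b$dlob$string),
        histogram = as.list(b$dlob$histogram),
        entropy = b$dlob$entropy,
        entropy_base = b$dlob$entropy_base,
        transition_mode = attr(b$dlob$transitions, "mode"),
        transitions = apply(unclass(b$dlob$transitions), 1L, as.list,
                            simplify = FALSE)
      )
    )
  })
  list(
    config = unclass(report$config),
    n_segments = report$n_segments,
    cv = list(scheme = report$partition$scheme,
              n_folds = report$partition$n_folds,
              fold_of = report$partition$fold_of),
    branches = branch_list,
    final = list(which = report$fot$which,
                 accuracies = as.list(report$fot$accuracies)),
    metrics = lapply(report$metrics, unclass)
  )
}
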