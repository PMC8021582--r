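# Pooling detections across channels and modalities, event-level scoring,
# and the crossover harness.

#' Pool per-channel detections
#'
#' Patient-level aggregation: the union of all channels' intervals, with
#' overlapping (or within-gap) intervals merged. Modality annotations are
#' preserved (merged intervals carry the union, e.g. `"seeg+video"`).
#'
#' @param per_channel a list of [anomaly_intervals()] tables on the same time
#'   base.
#' @param gap_tolerance merge intervals separated by at most this many samples
#'   (default 0).
#' @return one merged [anomaly_intervals()] table.
#' @export
pool_channels <- function(per_channel, gap_tolerance = 0) {
  per_channel <- Filter(function(x) nrow(x) > 0L, per_channel)
  if (!length(per_channel)) return(anomaly_intervals())
  all_iv <- do.call(rbind, lapply(per_channel, as.data.frame))
  iv <- anomaly_intervals(all_iv$start, all_iv$end, all_iv$peak_error,
                          all_iv$modality, all_iv$channel_id)
  merge_intervals(iv, gap_tolerance = gap_tolerance)
}

#' Pool SEEG and video detections
#'
#' Converts video intervals from frame indices to the SEEG sample time base
#' (`x * fs / fps`) and takes the union with the SEEG intervals. Union can
#' only add coverage, so pooled sensitivity is never below either modality's.
#'
#' @param seeg_intervals intervals in SEEG samples.
#' @param video_intervals intervals in video frames.
#' @param fs SEEG sampling rate (Hz).
#' @param fps video frame rate.
#' @param gap_tolerance merge gap in samples.
#' @return merged [anomaly_intervals()] in SEEG samples; merged intervals
#'   record which modalities contributed.
#' @export
pool_multimodal <- function(seeg_intervals, video_intervals, fs, fps,
                            gap_tolerance = 0) {
  v <- as.data.frame(video_intervals)
  if (nrow(v) > 0L) {
    scalef <- fs / fps
    v$start <- floor(v$start * scalef)
    v$end <- ceiling(v$end * scalef)
  }
  both <- rbind(as.data.frame(seeg_intervals), v)
  if (nrow(both) == 0L) return(anomaly_intervals())
  iv <- anomaly_intervals(both$start, both$end, both$peak_error,
                          both$modality, both$channel_id)
  merge_intervals(iv, gap_tolerance = gap_tolerance)
}

#' Match predicted intervals against truth events
#'
#' Any-overlap rule (default): a predicted interval is a true positive if it
#' overlaps at least one truth event; a truth event is detected if overlapped
#' by at least one prediction. One prediction covering several events counts
#' as one TP prediction but several detected events.
#'
#' @param predicted an [anomaly_intervals()] table (or data frame with
#'   `start`/`end`).
#' @param truth an [event_labels()] table on the same time base.
#' @param rule matching rule; only `"any-overlap"` is implemented (the field
#'   reports event-level hits without a stricter criterion).
#' @return a list with `tp_pred`, `fp_pred`, `detected_events`,
#'   `missed_events`.
#' @export
match_events <- function(predicted, truth, rule = "any-overlap") {
  if (!identical(rule, "any-overlap")) stop_param("unknown matching rule: ", rule)
  np <- nrow(predicted); nt <- nrow(truth)
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  pred_hit <- logical(np); truth_hit <- logical(nt)
  for (i in seq_len(np)) {
    hit <- overlaps(predicted$start[i], predicted$end[i], truth$start, truth$end)
    pred_hit[i] <- any(hit)
    truth_hit <- truth_hit | hit
  }
  list(tp_pred = sum(pred_hit), fp_pred = np - sum(pred_hit),
       detected_events = sum(truth_hit), missed_events = nt - sum(truth_hit))
}

#' Event-level evaluation report
#'
#' PPV (% of predicted intervals that hit a true event), sensitivity (% of
#' true events hit), and F1 (harmonic mean of the two as proportions). With
#' no predictions at all, PPV — and therefore F1 — is undefined and reported
#' as `NA` with `ppv_undefined = TRUE`, never as 0 or 100.
#'
#' @param predicted,truth as in [match_events()]; alternatively pass the
#'   counts from [match_events()] directly as `counts`.
#' @param mape_value optional reconstruction MAPE (%) to carry in the report.
#' @param condition label, e.g. `"seeg-dynamic"`, `"seeg-static"`, `"video"`,
#'   `"combined"`, `"crossover"`.
#' @param counts optional precomputed [match_events()] list.
#' @return a list of class `eval_report`.
#' @export
score_detection <- function(predicted = NULL, truth = NULL, mape_value = NA_real_,
                            condition = "seeg-dynamic", counts = NULL) {
  if (is.null(counts)) counts <- match_events(predicted, truth)
  n_pred <- counts$tp_pred + counts$fp_pred
  n_truth <- counts$detected_events + counts$missed_events
  ppv <- if (n_pred == 0L) NA_real_ else 100 * counts$tp_pred / n_pred
  sens <- if (n_truth == 0L) NA_real_ else 100 * counts$detected_events / n_truth
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_ else {
    2 * (ppv / 100) * (sens / 100) / ((ppv + sens) / 100)
  }
  structure(list(
    tp_pred = counts$tp_pred, fp_pred = counts$fp_pred,
    detected_events = counts$detected_events,
    missed_events = counts$missed_events,
    ppv = ppv, sensitivity = sens, f1 = f1, mape = mape_value,
    ppv_undefined = n_pred == 0L, condition = condition
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  ppv <- if (x$ppv_undefined) "undefined (no events detected)" else sprintf("%.1f%%", x$ppv)
  cat(sprintf("<eval_report: %s> PPV %s | sensitivity %s | F1 %s | MAPE %s\n",
              x$condition, ppv,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.1f%%", x$sensitivity)),
              ifelse(is.na(x$f1), "NA", sprintf("%.2f", x$f1)),
              ifelse(is.na(x$mape), "NA", sprintf("%.2f%%", x$mape))))
  cat(sprintf("  predictions: %d TP / %d FP; events: %d detected / %d missed\n",
              x$tp_pred, x$fp_pred, x$detected_events, x$missed_events))
  invisible(x)
}

#' Crossover detection run
#'
#' Applies a forecaster trained on one patient to the test segment of another
#' patient's recording, with every other condition (scaling, smoothing,
#' dynamic thresholding, pruning) identical to the within-patient path, and
#' scores the result. Probes how patient-specific the learned representation
#' is.
#'
#' @param model a fitted `seeg_forecaster` (from patient A).
#' @param series the full recording of patient B (one channel).
#' @param truth `event_labels` for patient B.
#' @param fconfig,dconfig,train_fraction,prune,lowpass_hz as in
#'   [detect_anomalies()].
#' @return an `eval_report` with `condition = "crossover"`.
#' @export
crossover_run <- function(model, series, truth, fconfig = model$config,
                          dconfig = NULL, train_fraction = 0.30,
                          prune = TRUE, lowpass_hz = 50) {
  if (!inherits(model, "seeg_forecaster")) stop_param("'model' must be a seeg_forecaster")
  if (!is.null(model$trained_on$fs) && model$trained_on$fs != series$fs) {
    stop_param(sprintf("sampling-rate mismatch: model %g Hz vs recording %g Hz",
                       model$trained_on$fs, series$fs))
  }
  res <- detect_anomalies(series, fconfig = fconfig, dconfig = dconfig,
                          model = model, train_fraction = train_fraction,
                          prune = prune, lowpass_hz = lowpass_hz)
  score_detection(res$intervals, truth, mape_value = res$mape,
                  condition = "crossover")
}

#' Summarise evaluation reports per condition
#'
#' Mean and standard error of the mean of PPV, sensitivity, F1 and MAPE per
#' condition. Undefined (NA) values are excluded, with the number of usable
#' reports per metric noted; a single report yields `NA` SEM.
#'
#' @param reports a list of `eval_report` objects.
#' @return a data frame with one row per condition and metric.
#' @export
aggregate_reports <- function(reports) {
  if (!length(reports)) stop_param("need at least one report")
  conds <- vapply(reports, function(r) r$condition, "")
  metrics <- c("ppv", "sensitivity", "f1", "mape")
  rows <- list()
  for (cond in unique(conds)) {
    sub <- reports[conds == cond]
    for (m in metrics) {
      v <- vapply(sub, function(r) as.numeric(r[[m]]), numeric(1))
      v_ok <- v[!is.na(v)]
      n <- length(v_ok)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, metric = m,
        mean = if (n) mean(v_ok) else NA_real_,
        sem = if (n > 1L) stats::sd(v_ok) / sqrt(n) else NA_real_,
        n = n, n_undefined = sum(is.na(v)))
    }
  }
  do.call(rbind, rows)
}
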