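# End-to-end detection for one channel and the synthetic monitoring-unit
# benchmark tying every stage together.

#' Detect anomalous events in one channel
#'
#' The full self-supervised path for a single channel: optional zero-phase
#' low-pass filtering, chronological train/test split, min-max scaling fitted
#' on the training segment only, forecaster training (or a supplied model, for
#' crossover runs), rolling one-step forecasts on the test segment, smoothed
#' absolute error, and threshold classification — the dynamic local threshold
#' with pruning by default, or the global static baseline.
#'
#' Detection is causal past the training segment: no stage uses samples beyond
#' the current sliding window, so chunked (streamed) processing gives
#' identical output to this batch call.
#'
#' @param series a [channel_series()] (raw; scaling happens inside).
#' @param fconfig a [forecast_config()].
#' @param dconfig a [dynamic_config()], or `NULL` (default) to size the
#'   sliding window from the sampling rate: 300 s of samples (capped at the
#'   error-series length), step half a window. The local threshold needs
#'   windows spanning several times the anomaly duration, so the window is a
#'   time scale, not a fixed point count.
#' @param method forecaster method when fitting here (`"ar"`, `"lstm"`,
#'   `"naive"`).
#' @param model optional pre-fitted `seeg_forecaster` (crossover contract:
#'   foreign models are allowed; the provenance mismatch is messaged).
#' @param threshold `"dynamic"` or `"static"`.
#' @param static_k static-baseline multiplier (default 2).
#' @param train_fraction opening fraction used for training (default 0.30).
#' @param prune apply error pruning after dynamic detection (default TRUE).
#' @param smoothing_span EWMA span; `NULL` uses 1% of the error-series length.
#' @param lowpass_hz low-pass cutoff, or `NULL` to skip filtering (e.g. for
#'   regularity traces whose Nyquist is below 50 Hz).
#' @param modality annotation on the output intervals.
#' @return a list of class `anomaly_detection`: `intervals` (full-series
#'   0-based sample indices), `errors` (the smoothed-error series), `mape`
#'   (held-out reconstruction MAPE, %), `model`, and `test_offset` (sample
#'   index where the error series starts).
#' @export
detect_anomalies <- function(series, fconfig = forecast_config(),
                             dconfig = NULL, method = "ar",
                             model = NULL,
                             threshold = c("dynamic", "static"),
                             static_k = 2, train_fraction = 0.30,
                             prune = TRUE, smoothing_span = NULL,
                             lowpass_hz = 50, modality = "seeg") {
  threshold <- match.arg(threshold)
  if (!inherits(series, "channel_series")) stop_param("'series' must be a channel_series")
  if (!is.null(lowpass_hz) && lowpass_hz < series$fs / 2) {
    series <- lowpass_filter(series, cutoff_hz = lowpass_hz)
  }
  l_b <- if (!is.null(model)) model$config$history_window else fconfig$history_window
  parts <- split_train_test(series, train_fraction,
                            min_train = l_b + fconfig$horizon + 1L)
  train <- scale_minmax(parts$train)
  test <- scale_minmax(parts$test, params = attr(train, "scaling"))
  if (is.null(model)) {
    model <- fit_forecaster(train, fconfig, method = method)
  }
  pred <- predict(model, test)
  actual <- test$values[(l_b + 1L):length(test$values)]
  es <- smoothed_error(actual, pred, span = smoothing_span)
  if (is.null(dconfig)) {
    ws <- max(10L, min(round(300 * series$fs), length(es$e_s)))
    dconfig <- dynamic_config(window_size = ws, step = max(1L, ws %/% 2L))
  }
  iv <- if (threshold == "static") {
    static_threshold_detect(es, k = static_k, modality = modality,
                            channel_id = series$channel_id)
  } else {
    detect_anomalous_sequences(es, dconfig,
                               prune_p = if (prune) dconfig$prune_p else NULL,
                               modality = modality,
                               channel_id = series$channel_id)
  }
  offset <- length(parts$train$values) + l_b   # error index 0 = this sample
  iv$start <- iv$start + offset
  iv$end <- iv$end + offset
  mape_val <- tryCatch(mape(actual, pred), seegwatch_data_error = function(e) NA_real_)
  structure(list(intervals = iv, errors = es, mape = mape_val, model = model,
                 test_offset = offset, threshold = threshold),
            class = "anomaly_detection")
}

#' @export
print.anomaly_detection <- function(x, ...) {
  cat(sprintf("<anomaly_detection: %s> %d interval(s), MAPE %.2f%%\n",
              x$threshold, nrow(x$intervals), x$mape))
  print(x$intervals)
  invisible(x)
}

#' Synthetic monitoring-unit benchmark
#'
#' The default desk-scale benchmark ("emu-default"): two spectral families of
#' two patients each (4 patients x 2 channels x 10 min at 256 Hz, 1--3 ictal
#' events per patient), run through five conditions mirroring the clinical
#' comparison: SEEG static baseline, SEEG dynamic thresholding, crossover
#' (family-A model applied to a family-B patient, plus a same-family control),
#' video regularity traces alone, and pooled video + SEEG.
#'
#' @param seed integer seed; the whole benchmark is reproducible from it.
#' @param method forecaster method (default `"ar"`, the deterministic
#'   baseline that keeps the benchmark inside CPU-minutes; `"lstm"` runs the
#'   neural forecaster).
#' @param duration_s per-recording length (default 600 s).
#' @param fs sampling rate (default 256 Hz).
#' @param n_channels channels per patient (default 2).
#' @param fconfig,dconfig configs shared across conditions.
#' @param conditions subset of
#'   `c("seeg-static", "seeg-dynamic", "crossover", "video", "combined")`.
#' @param fps video frame rate (default 30).
#' @return a list of class `emu_benchmark`: `reports` (per patient x
#'   condition `eval_report`s, plus `"crossover-control"` companions),
#'   `summary` (mean +/- SEM per condition), and `seed`.
#' @export
run_benchmark <- function(seed = 1L, method = "ar", duration_s = 600, fs = 256,
                          n_channels = 2L,
                          fconfig = forecast_config(seed = seed),
                          dconfig = NULL,
                          conditions = c("seeg-static", "seeg-dynamic",
                                         "crossover", "video", "combined"),
                          fps = 30) {
  famA <- family_spec("A")
  famB <- family_spec("B")
  patients <- c(
    gen_patient_family(famA, 2L, seed = seed, n_channels = n_channels,
                       fs = fs, duration_s = duration_s),
    gen_patient_family(famB, 2L, seed = seed + 104729L,
                       n_channels = n_channels, fs = fs,
                       duration_s = duration_s)
  )
  reports <- list()
  det_dynamic <- vector("list", length(patients))
  mape_dyn <- numeric(length(patients))

  for (p in seq_along(patients)) {
    pat <- patients[[p]]
    runs <- lapply(pat$channels, detect_anomalies, fconfig = fconfig,
                   dconfig = dconfig, method = method)
    det_dynamic[[p]] <- pool_channels(lapply(runs, function(r) r$intervals))
    mape_dyn[p] <- mean(vapply(runs, function(r) r$mape, numeric(1)), na.rm = TRUE)
    if ("seeg-dynamic" %in% conditions) {
      reports[[length(reports) + 1L]] <-
        score_detection(det_dynamic[[p]], pat$labels, mape_value = mape_dyn[p],
                        condition = "seeg-dynamic")
    }
    if ("seeg-static" %in% conditions) {
      sruns <- lapply(pat$channels, detect_anomalies, fconfig = fconfig,
                      dconfig = dconfig, method = method, threshold = "static")
      pooled <- pool_channels(lapply(sruns, function(r) r$intervals))
      reports[[length(reports) + 1L]] <-
        score_detection(pooled, pat$labels,
                        mape_value = mean(vapply(sruns, function(r) r$mape,
                                                 numeric(1)), na.rm = TRUE),
                        condition = "seeg-static")
    }
  }

  if ("crossover" %in% conditions) {
    # donor models from A1 and B1 (channel 1); each is applied to the second
    # patient of the other family (crossover) and of its own family
    # (crossover-control), so the comparison contrasts model mismatch on the
    # same target recordings with all other conditions identical
    donor_model <- function(p) {
      ch <- lowpass_filter(patients[[p]]$channels[[1]])
      parts <- split_train_test(ch, 0.30,
                                min_train = fconfig$history_window + 2L)
      fit_forecaster(scale_minmax(parts$train), fconfig, method = method)
    }
    mA <- donor_model(1L); mB <- donor_model(3L)
    pairs <- list(list(m = mA, p = 4L, cond = "crossover"),
                  list(m = mB, p = 2L, cond = "crossover"),
                  list(m = mA, p = 2L, cond = "crossover-control"),
                  list(m = mB, p = 4L, cond = "crossover-control"))
    for (target in pairs) {
      pat <- patients[[target$p]]
      runs <- lapply(pat$channels, function(ch) {
        suppressMessages(
          detect_anomalies(ch, fconfig = fconfig, dconfig = dconfig,
                           model = target$m))
      })
      pooled <- pool_channels(lapply(runs, function(r) r$intervals))
      reports[[length(reports) + 1L]] <-
        score_detection(pooled, pat$labels,
                        mape_value = mean(vapply(runs, function(r) r$mape,
                                                 numeric(1)), na.rm = TRUE),
                        condition = target$cond)
    }
  }

  if (any(c("video", "combined") %in% conditions)) {
    for (p in seq_along(patients)) {
      pat <- patients[[p]]
      frame_truth <- event_labels(floor(pat$labels$start * fps / fs),
                                  ceiling(pat$labels$end * fps / fs),
                                  fs = fps, source = "synthetic-truth")
      vid <- gen_regularity_trace(duration_s, fps = fps, events = frame_truth,
                                  seed = seed + 31L * p)
      vdet <- detect_video_anomalies(vid$trace, fconfig = fconfig,
                                     dconfig = dconfig, method = method)
      if ("video" %in% conditions) {
        reports[[length(reports) + 1L]] <-
          score_detection(vdet$intervals, frame_truth, mape_value = vdet$mape,
                          condition = "video")
      }
      if ("combined" %in% conditions) {
        pooled <- pool_multimodal(det_dynamic[[p]], vdet$intervals,
                                  fs = fs, fps = fps)
        reports[[length(reports) + 1L]] <-
          score_detection(pooled, pat$labels, mape_value = mape_dyn[p],
                          condition = "combined")
      }
    }
  }

  structure(list(reports = reports, summary = aggregate_reports(reports),
                 seed = seed),
            class = "emu_benchmark")
}

#' @export
print.emu_benchmark <- function(x, ...) {
  cat(sprintf("<emu_benchmark> seed %d, %d report(s)\n", x$seed,
              length(x$reports)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
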