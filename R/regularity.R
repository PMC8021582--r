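# Regularity scoring: per-frame reconstruction errors -> abnormality and
# regularity scores, and the video detection path (identical forecasting /
# thresholding machinery as SEEG, applied to the regularity trace).

#' Per-frame reconstruction errors
#'
#' `e(t)` is the sum over pixels of the per-pixel reconstruction error of
#' frame `t` (squared by default, absolute optionally).
#'
#' @param model a trained [train_autoencoder()] result, or — for testing and
#'   for user-supplied reconstructions — a function mapping the `(H, W, N)`
#'   frame array to a reconstruction array of the same shape.
#' @param frames a [frame_sequence()].
#' @param convention `"squared"` or `"absolute"`; defaults to the model's
#'   configured convention (squared for function stubs).
#' @return nonnegative numeric vector of per-frame errors.
#' @export
frame_errors <- function(model, frames, convention = NULL) {
  if (!inherits(frames, "frame_sequence")) stop_param("'frames' must be a frame_sequence")
  if (is.function(model)) {
    recon <- model(frames$frames)
    convention <- convention %||% "squared"
  } else if (inherits(model, "conv_lstm_autoencoder")) {
    recon <- reconstruct_frames(model, frames)
    convention <- convention %||% model$config$error_convention
  } else stop_param("'model' must be a conv_lstm_autoencoder or a function")
  if (!identical(dim(recon), dim(frames$frames))) {
    stop_param("reconstruction shape does not match the input frames")
  }
  diffs <- recon - frames$frames
  per_px <- if (convention == "absolute") abs(diffs) else diffs^2
  apply(per_px, 3L, sum)
}

#' Regularity score series
#'
#' Min-max normalisation of the per-frame reconstruction errors:
#' `a(t) = (e(t) - min(e)) / max(e)` (abnormality) and `s(t) = 1 - a(t)`
#' (regularity). A constant error series — including all-zero errors — has no
#' abnormality signal and scores `s == 1` everywhere.
#'
#' @param e_t nonnegative per-frame reconstruction errors.
#' @param fps frame rate the scores refer to.
#' @return an object of class `regularity_series` with fields `e_t`, `a_t`,
#'   `s_t`, `fps`.
#' @export
regularity_score <- function(e_t, fps = 30) {
  if (length(e_t) < 1L) stop_param("need at least one error value")
  if (any(!is.finite(e_t)) || any(e_t < 0)) {
    stop_data("frame errors must be finite and nonnegative")
  }
  mx <- max(e_t)
  a <- if (mx == 0 || mx == min(e_t)) rep(0, length(e_t)) else (e_t - min(e_t)) / mx
  structure(list(e_t = as.numeric(e_t), a_t = a, s_t = 1 - a, fps = fps),
            class = "regularity_series")
}

#' @export
print.regularity_series <- function(x, ...) {
  cat(sprintf("<regularity_series> %d frame(s) @ %g fps, min s = %.4f\n",
              length(x$s_t), x$fps, min(x$s_t)))
  invisible(x)
}

#' Write / read a regularity series as CSV
#'
#' Columns `frame_index` (0-based), `e_t`, `s_t`; lets users supply
#' precomputed regularity scores and skip the autoencoder entirely.
#'
#' @param reg a [regularity_score()] result.
#' @param path CSV path.
#' @param fps frame rate to attach on read.
#' @return `path` / a `regularity_series`.
#' @export
write_regularity <- function(reg, path) {
  utils::write.csv(data.frame(frame_index = seq_along(reg$e_t) - 1L,
                              e_t = reg$e_t, s_t = reg$s_t),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regularity
#' @export
read_regularity <- function(path, fps = 30) {
  d <- utils::read.csv(path)
  if (!all(c("e_t", "s_t") %in% names(d))) {
    stop_data("regularity CSV must have e_t and s_t columns")
  }
  structure(list(e_t = d$e_t, a_t = 1 - d$s_t, s_t = d$s_t, fps = fps),
            class = "regularity_series")
}

#' Detect anomalies in a video regularity trace
#'
#' Feeds the regularity score series through the identical path used for SEEG
#' channels — forecaster, smoothed error, dynamic threshold, pruning — and
#' returns intervals index-aligned to frames with `modality = "video"`.
#'
#' @param reg a `regularity_series` (or numeric `s_t` vector).
#' @param fps frame rate if `reg` is a bare vector.
#' @param fconfig a [forecast_config()].
#' @param dconfig a [dynamic_config()], or `NULL` to size the window from the
#'   frame rate as in [detect_anomalies()].
#' @param method forecaster method (default `"ar"`).
#' @param train_fraction opening fraction used to fit the forecaster.
#' @param prune apply error pruning (default `TRUE`).
#' @param channel_id annotation for the output intervals.
#' @return a [detect_anomalies()] result (intervals in 0-based frame indices).
#' @export
detect_video_anomalies <- function(reg, fps = 30,
                                   fconfig = forecast_config(),
                                   dconfig = NULL,
                                   method = "ar", train_fraction = 0.30,
                                   prune = TRUE, channel_id = "video") {
  s_t <- if (inherits(reg, "regularity_series")) reg$s_t else as.numeric(reg)
  if (inherits(reg, "regularity_series")) fps <- reg$fps
  series <- channel_series(s_t, fs = fps, patient_id = "video",
                           channel_id = channel_id)
  detect_anomalies(series, fconfig = fconfig, dconfig = dconfig,
                   method = method, train_fraction = train_fraction,
                   prune = prune, lowpass_hz = NULL, modality = "video")
}
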