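#' Uniformly sampled single-channel series
#'
#' The basic container for one SEEG channel (or a video regularity-score
#' trace): a finite numeric vector plus sampling rate and provenance. All
#' downstream stages (filtering, scaling, forecasting, thresholding) consume
#' and return `channel_series` objects.
#'
#' @param values finite numeric vector, length >= 1.
#' @param fs sampling rate in Hz (> 0). For video traces this is the frame
#'   rate in frames per second.
#' @param patient_id,channel_id provenance strings.
#' @param start_index 0-based sample offset of `values[1]` within the original
#'   recording (used when a series is split).
#' @return an object of class `channel_series`.
#' @export
channel_series <- function(values, fs, patient_id = "unknown",
                           channel_id = "ch1", start_index = 0L) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop_param("a channel series needs at least one sample")
  if (any(!is.finite(values))) stop_data("channel series contains non-finite values")
  assert_scalar_number(fs, "fs", lower = .Machine$double.eps)
  structure(
    list(values = values, fs = fs,
         patient_id = as.character(patient_id),
         channel_id = as.character(channel_id),
         start_index = as.integer(start_index)),
    class = "channel_series"
  )
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf(
    "<channel_series> %s/%s: %d samples @ %g Hz (%.1f s), range [%.4g, %.4g]\n",
    x$patient_id, x$channel_id, length(x$values), x$fs,
    length(x$values) / x$fs, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.channel_series <- function(x) length(x$values)

#' Labelled event intervals
#'
#' Ground-truth (or predicted) event intervals for one recording: half-open
#' `[start, end)` sample indices, 0-based, sorted and non-overlapping after
#' normalisation.
#'
#' @param start,end numeric vectors of interval bounds (samples).
#' @param fs sampling rate the indices refer to.
#' @param source provenance string, e.g. `"consensus"` or `"synthetic-truth"`.
#' @param strict if `TRUE`, inverted or overlapping intervals raise an error;
#'   otherwise they are normalised (sorted, merged) with a warning.
#' @return an object of class `event_labels` (a data frame with attributes
#'   `fs` and `source`).
#' @export
event_labels <- function(start = numeric(), end = numeric(), fs = 1,
                         source = "consensus", strict = FALSE) {
  if (length(start) != length(end)) stop_param("start and end lengths differ")
  assert_scalar_number(fs, "fs", lower = .Machine$double.eps)
  if (any(end <= start)) {
    if (strict) stop_data("inverted interval (end <= start) in strict mode")
    warning("dropping/normalising inverted intervals")
    keep <- end > start
    start <- start[keep]; end <- end[keep]
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  # merge overlaps
  if (length(start) > 1L) {
    overlapping <- any(start[-1] < end[-length(end)])
    if (overlapping && strict) stop_data("overlapping intervals in strict mode")
    if (overlapping) warning("merging overlapping intervals")
    i <- 1L
    while (i < length(start)) {
      if (start[i + 1L] <= end[i]) {
        end[i] <- max(end[i], end[i + 1L])
        start <- start[-(i + 1L)]; end <- end[-(i + 1L)]
      } else i <- i + 1L
    }
  }
  out <- data.frame(start = as.numeric(start), end = as.numeric(end))
  attr(out, "fs") <- fs
  attr(out, "source") <- source
  class(out) <- c("event_labels", "data.frame")
  out
}

#' @export
print.event_labels <- function(x, ...) {
  cat(sprintf("<event_labels> %d event(s) @ %g Hz [%s]\n",
              nrow(x), attr(x, "fs"), attr(x, "source")))
  if (nrow(x) > 0L) print.data.frame(as.data.frame(x), ...)
  invisible(x)
}
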