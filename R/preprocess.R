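# Preprocessing: zero-phase FIR low-pass, (-1, 1) min-max scaling, and the
# chronological train/test split.

# Windowed-sinc (Hamming) low-pass kernel with unity DC gain. Odd length so
# the group delay (ntaps-1)/2 is an integer number of samples.
fir_lowpass_kernel <- function(cutoff_hz, fs, transition_hz = 12.5) {
  ntaps <- ceiling(3.3 * fs / transition_hz)       # Hamming main-lobe rule
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  n <- seq_len(ntaps) - 1 - m
  h <- 2 * cutoff_hz / fs * sinc(2 * cutoff_hz * n / fs)
  w <- 0.54 + 0.46 * cos(pi * n / m)               # Hamming, centred
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase FIR low-pass filter
#'
#' One-pass, non-causal low-pass filtering with a windowed-sinc (Hamming) FIR
#' kernel. The symmetric kernel is applied once by convolution and the group
#' delay is compensated exactly, so the output has zero phase distortion.
#' Edges are handled by reflect-padding the series by half the kernel length.
#'
#' @param series a [channel_series()].
#' @param cutoff_hz -6 dB cutoff frequency in Hz (default 50).
#' @param transition_hz transition bandwidth controlling the kernel length
#'   (default 12.5 Hz; the kernel has about `3.3 * fs / transition_hz` taps).
#' @return a `channel_series` of the same length and sampling rate.
#' @export
lowpass_filter <- function(series, cutoff_hz = 50, transition_hz = 12.5) {
  if (!inherits(series, "channel_series")) stop_param("'series' must be a channel_series")
  assert_scalar_number(cutoff_hz, "cutoff_hz", lower = .Machine$double.eps)
  if (cutoff_hz >= series$fs / 2) {
    stop_param("cutoff_hz must be below the Nyquist frequency fs/2")
  }
  h <- fir_lowpass_kernel(cutoff_hz, series$fs, transition_hz)
  x <- series$values
  m <- (length(h) - 1) / 2
  if (length(x) <= length(h)) {
    stop_param("series shorter than the filter kernel (", length(h), " taps)")
  }
  # reflect padding by m on both sides, single forward convolution, then the
  # central slice compensates the m-sample group delay
  xp <- c(rev(x[seq_len(m) + 1]), x, x[length(x) - seq_len(m)])
  y <- stats::filter(xp, h, method = "convolution", sides = 1)
  ntaps <- length(h)
  y <- as.numeric(y[ntaps:(ntaps + length(x) - 1)])
  out <- series
  out$values <- y
  out
}

# Evaluate the complex frequency response of an FIR kernel at freqs_hz (used
# by tests as an independent oracle and exported for audit).

#' FIR frequency response
#'
#' Magnitude of the filter's frequency response at the requested frequencies,
#' evaluated directly from the kernel taps.
#'
#' @param freqs_hz frequencies in Hz.
#' @param fs sampling rate.
#' @param cutoff_hz,transition_hz kernel parameters as in [lowpass_filter()].
#' @return numeric vector of |H(f)|.
#' @export
lowpass_response <- function(freqs_hz, fs, cutoff_hz = 50, transition_hz = 12.5) {
  h <- fir_lowpass_kernel(cutoff_hz, fs, transition_hz)
  k <- seq_along(h) - 1
  vapply(freqs_hz, function(f) {
    Mod(sum(h * exp(-2i * pi * f * k / fs)))
  }, numeric(1))
}

#' Min-max scaling to (-1, 1)
#'
#' Affine scaling so the training minimum maps to -1 and the maximum to +1.
#' The fitted parameters are recorded on the result (attribute `"scaling"`)
#' and can be reapplied to later segments via `params`, so test data is scaled
#' with train-segment statistics and never leaks its own extremes.
#'
#' @param series a [channel_series()].
#' @param params optional scaling parameters from a previous call
#'   (`attr(scaled, "scaling")`); when supplied they are reused verbatim.
#' @return a scaled `channel_series` with attribute `"scaling"` =
#'   `list(min = , max = )`. A constant series (no fitted range) maps to all
#'   zeros.
#' @export
scale_minmax <- function(series, params = NULL) {
  if (!inherits(series, "channel_series")) stop_param("'series' must be a channel_series")
  x <- series$values
  if (is.null(params)) params <- list(min = min(x), max = max(x))
  out <- series
  if (params$max == params$min) {
    out$values <- rep(0, length(x))
  } else {
    out$values <- 2 * (x - params$min) / (params$max - params$min) - 1
  }
  attr(out, "scaling") <- params
  out
}

#' Chronological train/test split
#'
#' Splits a series into a contiguous training prefix and testing suffix. The
#' split is always chronological (train precedes test) so no future samples
#' leak into training; concatenating the two parts reconstructs the input.
#'
#' @param series a [channel_series()].
#' @param train_fraction fraction of samples assigned to training. The
#'   monitoring protocol this emulates uses 0.20--0.50; default 0.30.
#' @param min_train minimum admissible training length in samples (e.g. the
#'   forecaster's history window plus horizon).
#' @return `list(train = , test = )` of `channel_series`; `start_index` on the
#'   test part records its offset.
#' @export
split_train_test <- function(series, train_fraction = 0.30, min_train = 2L) {
  if (!inherits(series, "channel_series")) stop_param("'series' must be a channel_series")
  assert_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_param("train_fraction must lie strictly between 0 and 1")
  }
  n <- length(series$values)
  sp <- floor(n * train_fraction)
  if (sp < min_train) {
    stop_param("training segment too short (", sp, " < ", min_train, " samples)")
  }
  if (sp >= n) stop_param("no samples left for testing")
  train <- series; test <- series
  train$values <- series$values[seq_len(sp)]
  test$values <- series$values[(sp + 1):n]
  test$start_index <- series$start_index + sp
  list(train = train, test = test)
}
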