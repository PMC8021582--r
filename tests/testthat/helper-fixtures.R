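# Shared fixtures, all built in code at test time.

sine_series <- function(freq_hz = 4, fs = 64, duration_s = 40, amp = 1,
                        patient = "sim", channel = "sine") {
  tt <- (seq_len(round(duration_s * fs)) - 1) / fs
  channel_series(amp * sin(2 * pi * freq_hz * tt), fs,
                 patient_id = patient, channel_id = channel)
}

# small deterministic forecaster config for neural tests
lstm_test_config <- function(seed = 1L, ...) {
  forecast_config(hidden_units = 32L, history_window = 32L,
                  learning_rate = 0.02, batch_size = 16L, seed = seed, ...)
}

# random non-overlapping half-open intervals over [0, n) with their peak
# errors, for pruning tests
random_interval_set <- function(n = 400L, k = 5L) {
  e <- abs(stats::rnorm(n, 0, 0.5))
  bounds <- sort(sample.int(n - 1L, 2L * k))
  starts <- bounds[seq(1L, 2L * k, 2L)] - 1L
  ends <- bounds[seq(2L, 2L * k, 2L)]
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  for (i in seq_along(starts)) {
    e[(starts[i] + 1L):ends[i]] <- e[(starts[i] + 1L):ends[i]] +
      stats::runif(1, 0.5, 5)
  }
  peaks <- vapply(seq_along(starts),
                  function(i) max(e[(starts[i] + 1L):ends[i]]), numeric(1))
  list(iv = anomaly_intervals(starts, ends, peaks), e = e)
}

# independent brute-force threshold search (the A1 oracle): plain loops, no
# shared code with the implementation
brute_threshold <- function(w, zs, penalized) {
  best <- NULL
  for (z in zs) {
    mu <- mean(w)
    sg <- sqrt(mean((w - mu)^2))
    eps <- mu + z * sg
    obj <- 0
    if (sg > 0) {
      ab <- w > eps
      if (any(ab)) {
        kept <- w[!ab]
        km <- mean(kept)
        ks <- sqrt(mean((kept - km)^2))
        obj <- (mu - km) / mu + (sg - ks) / sg
        if (penalized) {
          r <- rle(ab)
          obj <- obj / (sum(ab) + sum(r$values)^2)
        }
      }
    }
    if (is.null(best) || obj >= best$obj) best <- list(z = z, obj = obj, eps = eps)
  }
  best
}

# independent hand-stepped sorted-maxima pruning (the A6 oracle): returns the
# indices of surviving intervals
brute_prune <- function(peaks, outside_max, p) {
  o <- order(peaks, decreasing = TRUE)
  m <- c(peaks[o], outside_max)
  d <- numeric(length(peaks))
  for (i in seq_along(peaks)) {
    d[i] <- if (m[i] > 0) (m[i] - m[i + 1]) / m[i] else 0
  }
  keep <- which(d > p)
  if (!length(keep)) return(integer(0))
  sort(o[seq_len(max(keep))])
}
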