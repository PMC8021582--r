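# Nonparametric dynamic thresholding of smoothed forecast errors.
#
# Within each sliding window the threshold eps = mu + z*sigma is chosen (over
# a grid of z) to maximise the percent decrease in the window's mean and
# standard deviation of the smoothed error when the values above eps are
# excluded, optionally penalised by the number of excluded points and runs.
# Error residuals are typically non-Gaussian, which is why no parametric tail
# is assumed anywhere. Conventions pinned here: exceedance is strict
# (e_s > eps), the retained set is its complement (e_s <= eps), and sigma is
# the population (divide-by-n) standard deviation.

#' Dynamic-threshold configuration
#'
#' @param window_size sliding-window length in error samples (default 2048).
#' @param step window step (default `window_size / 2`).
#' @param z_grid candidate z multipliers (default `seq(2, 10, by = 0.5)`).
#' @param penalized if `TRUE` the objective is divided by
#'   `(#excluded points + #excluded runs^2)`, discouraging thresholds that
#'   call large swaths anomalous. Default `FALSE`: ictal events span
#'   thousands of samples at SEEG rates, and the count penalty then favours
#'   thresholds that shave event tops (which pruning subsequently discards)
#'   over thresholds that separate events from background.
#' @param prune_p pruning fraction: anomalies whose peak error is not
#'   separated from the next-largest peak by more than this relative drop are
#'   reclassified as normal (default 0.10).
#' @param gap_tolerance merge flagged runs closer than this many samples
#'   (default 0).
#' @return a validated list of class `dynamic_config`.
#' @export
dynamic_config <- function(window_size = 2048L, step = window_size %/% 2L,
                           z_grid = seq(2, 10, by = 0.5), penalized = FALSE,
                           prune_p = 0.10, gap_tolerance = 0L) {
  assert_scalar_number(window_size, "window_size", lower = 10)
  assert_scalar_number(step, "step", lower = 1)
  assert_scalar_number(prune_p, "prune_p", lower = 0, upper = 1)
  if (!is.numeric(z_grid) || length(z_grid) < 1L || any(z_grid < 0)) {
    stop_param("z_grid must be a nonempty vector of nonnegative multipliers")
  }
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 z_grid = sort(z_grid), penalized = isTRUE(penalized),
                 prune_p = prune_p, gap_tolerance = as.integer(gap_tolerance)),
            class = "dynamic_config")
}

#' Threshold objective for one window
#'
#' Evaluates the self-supervised objective at `eps = mu + z * sigma`:
#' `delta_mu / mu + delta_sigma / sigma`, where `delta_mu` and `delta_sigma`
#' are the decreases in window mean and (population) standard deviation after
#' excluding values strictly above `eps`. The penalised form divides by
#' `(#excluded points + #excluded contiguous runs^2)`. Windows with zero
#' spread, or a threshold no point exceeds, score 0.
#'
#' @param e_window numeric window of smoothed errors (length >= 2).
#' @param z nonnegative multiplier.
#' @param penalized logical.
#' @return a list with `epsilon`, `objective`, and diagnostics (`mu`, `sigma`,
#'   `delta_mu`, `delta_sigma`, `n_anom_points`, `n_anom_seqs`).
#' @export
threshold_objective <- function(e_window, z, penalized = TRUE) {
  if (length(e_window) < 2L) stop_param("window must contain at least 2 values")
  assert_scalar_number(z, "z", lower = 0)
  mu <- mean(e_window); sigma <- pop_sd(e_window)
  out <- list(epsilon = mu, objective = 0, mu = mu, sigma = sigma,
              delta_mu = 0, delta_sigma = 0, n_anom_points = 0L,
              n_anom_seqs = 0L, degenerate = FALSE)
  if (sigma == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  eps <- mu + z * sigma
  out$epsilon <- eps
  above <- e_window > eps
  if (!any(above)) return(out)
  kept <- e_window[!above]
  delta_mu <- mu - mean(kept)
  delta_sigma <- sigma - pop_sd(kept)
  n_pts <- sum(above)
  n_seq <- nrow(runs_to_intervals(above))
  obj <- delta_mu / mu + delta_sigma / sigma
  if (penalized) obj <- obj / (n_pts + n_seq^2)
  out$objective <- obj
  out$delta_mu <- delta_mu; out$delta_sigma <- delta_sigma
  out$n_anom_points <- as.integer(n_pts); out$n_anom_seqs <- as.integer(n_seq)
  out
}

#' Optimal local threshold for one window
#'
#' Maximises [threshold_objective()] over the configured z grid. Ties break
#' toward the larger z (the more conservative threshold, flagging fewer
#' points). A window with zero spread returns a no-anomaly decision.
#'
#' @param e_window numeric window of smoothed errors.
#' @param config a [dynamic_config()].
#' @return a list of class `threshold_decision`: the winning `z`, `epsilon`,
#'   `objective`, and the diagnostics of [threshold_objective()].
#' @export
find_dynamic_threshold <- function(e_window, config = dynamic_config()) {
  best <- NULL
  for (z in config$z_grid) {           # ascending: >= hands ties to larger z
    cand <- threshold_objective(e_window, z, penalized = config$penalized)
    if (is.null(best) || cand$objective >= best$objective) {
      best <- cand
      best$z <- z
    }
  }
  class(best) <- "threshold_decision"
  best
}

#' @export
print.threshold_decision <- function(x, ...) {
  cat(sprintf(
    "<threshold_decision> z=%.2f eps=%.5g objective=%.5g (%d pts, %d runs)\n",
    x$z, x$epsilon, x$objective, x$n_anom_points, x$n_anom_seqs))
  invisible(x)
}

as_error_vector <- function(e_s) {
  if (inherits(e_s, "smoothed_error_series")) e_s$e_s else as.numeric(e_s)
}

#' Detect anomalous sequences with the dynamic threshold
#'
#' Slides a window across the smoothed error series, finds the optimal local
#' threshold in each window, flags the points exceeding it, takes the union of
#' flags across overlapping windows, and merges contiguous flagged runs into
#' half-open intervals annotated with their peak error. A final partial window
#' anchored at the end of the series ensures the tail is always covered.
#'
#' Pruning (when `prune_p` is non-`NULL`) is applied within each window, on
#' that window's flagged runs against that window's errors, before the union —
#' matching the source method, where weak local exceedances whose peaks are
#' not separated from the window's remaining errors are reclassified as
#' normal. The standalone [prune_anomalies()] remains available for global
#' post-hoc pruning.
#'
#' @param e_s a [smoothed_error()] result or numeric vector.
#' @param config a [dynamic_config()].
#' @param prune_p per-window pruning fraction (`NULL` disables pruning).
#' @param modality,channel_id annotations carried on the output intervals.
#' @return an [anomaly_intervals()] table in 0-based error-sample indices.
#' @export
detect_anomalous_sequences <- function(e_s, config = dynamic_config(),
                                       prune_p = NULL,
                                       modality = "seeg", channel_id = NA) {
  e <- as_error_vector(e_s)
  n <- length(e)
  if (n < config$window_size) {
    stop_param("error series shorter than the sliding window (", n, " < ",
               config$window_size, ")")
  }
  starts <- seq.int(1L, n - config$window_size + 1L, by = config$step)
  if (starts[length(starts)] + config$window_size - 1L < n) {
    starts <- c(starts, n - config$window_size + 1L)
  }
  flag <- logical(n)
  for (s in starts) {
    idx <- s:(s + config$window_size - 1L)
    ew <- e[idx]
    dec <- find_dynamic_threshold(ew, config)
    if (dec$n_anom_points > 0L) {
      runs <- runs_to_intervals(ew > dec$epsilon)
      if (!is.null(prune_p) && nrow(runs) > 0L) {
        peaks <- vapply(seq_len(nrow(runs)),
                        function(i) max(ew[(runs[i, 1] + 1L):runs[i, 2]]),
                        numeric(1))
        local_iv <- anomaly_intervals(runs[, 1], runs[, 2], peaks)
        kept <- prune_anomalies(local_iv, ew, p = prune_p)
        runs <- cbind(start = kept$start, end = kept$end)
      }
      for (i in seq_len(nrow(runs))) {
        flag[idx[(runs[i, 1] + 1L):runs[i, 2]]] <- TRUE
      }
    }
  }
  iv <- runs_to_intervals(flag)
  if (nrow(iv) == 0L) {
    return(anomaly_intervals(modality = modality, channel_id = channel_id))
  }
  peaks <- vapply(seq_len(nrow(iv)),
                  function(i) max(e[(iv[i, 1] + 1L):iv[i, 2]]), numeric(1))
  out <- anomaly_intervals(iv[, 1], iv[, 2], peaks, modality, channel_id)
  merge_intervals(out, gap_tolerance = config$gap_tolerance)
}

#' Prune weak anomalies
#'
#' Post-hoc reclassification: interval peak errors are sorted in descending
#' order `m_1 >= ... >= m_k`, with `m_(k+1)` the largest smoothed error
#' outside all intervals (0 if none). Relative drops
#' `d_i = (m_i - m_(i+1)) / m_i` are stepped through and `i*` is the largest
#' `i` with `d_i > p`; intervals whose peaks rank at or above `i*` remain
#' anomalies, the rest are reclassified as normal. If no drop exceeds `p`,
#' every interval is reclassified.
#'
#' @param intervals an [anomaly_intervals()] table with `peak_error` filled.
#' @param e_s the smoothed error series the intervals refer to.
#' @param p relative-drop cutoff (default 0.10).
#' @return the retained subset of `intervals`.
#' @export
prune_anomalies <- function(intervals, e_s, p = 0.10) {
  assert_scalar_number(p, "p", lower = 0, upper = 1)
  if (nrow(intervals) == 0L) return(intervals)
  e <- as_error_vector(e_s)
  inside <- logical(length(e))
  for (i in seq_len(nrow(intervals))) {
    inside[(intervals$start[i] + 1L):intervals$end[i]] <- TRUE
  }
  m_next <- if (all(inside)) 0 else max(e[!inside])
  ord <- order(intervals$peak_error, decreasing = TRUE)
  m <- c(intervals$peak_error[ord], m_next)
  k <- nrow(intervals)
  d <- ifelse(m[seq_len(k)] > 0, (m[seq_len(k)] - m[seq_len(k) + 1L]) / m[seq_len(k)], 0)
  keep_rank <- which(d > p)
  if (length(keep_rank) == 0L) {
    return(intervals[integer(0), , drop = FALSE])
  }
  i_star <- max(keep_rank)
  intervals[sort(ord[seq_len(i_star)]), , drop = FALSE]
}

#' Static-threshold baseline detection
#'
#' The conventional label-free baseline: one global threshold
#' `mean(e_s) + k * sd(e_s)` (population sd), contiguous exceedance runs
#' merged into intervals. Used as the comparison condition for the dynamic
#' method.
#'
#' @param e_s a [smoothed_error()] result or numeric vector (length >= 2).
#' @param k multiplier (default 2).
#' @param modality,channel_id annotations carried on the output.
#' @return an [anomaly_intervals()] table.
#' @export
static_threshold_detect <- function(e_s, k = 2, modality = "seeg",
                                    channel_id = NA) {
  e <- as_error_vector(e_s)
  if (length(e) < 2L) stop_param("error series must contain at least 2 values")
  sigma <- pop_sd(e)
  if (sigma == 0) return(anomaly_intervals(modality = modality, channel_id = channel_id))
  thr <- mean(e) + k * sigma
  iv <- runs_to_intervals(e > thr)
  if (nrow(iv) == 0L) {
    return(anomaly_intervals(modality = modality, channel_id = channel_id))
  }
  peaks <- vapply(seq_len(nrow(iv)),
                  function(i) max(e[(iv[i, 1] + 1L):iv[i, 2]]), numeric(1))
  anomaly_intervals(iv[, 1], iv[, 2], peaks, modality, channel_id)
}
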