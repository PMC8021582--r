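#' @keywords internal
"_PACKAGE"

# Run code with a local RNG seed, restoring the caller's RNG state afterwards.
# All stochastic entry points in the package funnel through this so that a
# (params, seed) pair is a pure function of its arguments.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("seegwatch_parameter_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("seegwatch_data_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_param(sprintf("'%s' must be a finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Population (divide-by-n) standard deviation: the convention pinned for every
# threshold computation in the package.
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NaN)
  sqrt(sum((x - mean(x))^2) / n)
}

# ---- half-open interval helpers ------------------------------------------
# All user-facing intervals are half-open [start, end) in 0-based indices.

#' Construct an anomaly-interval table
#'
#' Detection output throughout the package is a data frame of half-open
#' `[start, end)` intervals in 0-based sample (or frame) indices, annotated
#' with the peak smoothed error inside each interval, the source modality, and
#' the channel that produced it.
#'
#' @param start,end integer vectors, `start < end`, 0-based half-open.
#' @param peak_error nonnegative numeric vector (peak smoothed error inside).
#' @param modality `"seeg"` or `"video"` (recycled).
#' @param channel_id character (recycled).
#' @return a `data.frame` with class `anomaly_intervals`.
#' @export
anomaly_intervals <- function(start = integer(), end = integer(),
                              peak_error = numeric(), modality = character(),
                              channel_id = character()) {
  n <- length(start)
  if (length(end) != n) stop_param("start and end must have equal length")
  if (n > 0L && any(end <= start)) stop_param("intervals must satisfy start < end")
  if (length(peak_error) == 0L) peak_error <- rep(NA_real_, n)
  if (length(modality) == 0L) modality <- rep(NA_character_, n)
  if (length(channel_id) == 0L) channel_id <- rep(NA_character_, n)
  out <- data.frame(
    start = as.numeric(start), end = as.numeric(end),
    peak_error = rep_len(as.numeric(peak_error), n),
    modality = rep_len(as.character(modality), n),
    channel_id = rep_len(as.character(channel_id), n),
    stringsAsFactors = FALSE
  )
  if (n > 0L) out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("anomaly_intervals", "data.frame")
  out
}

# Merge sorted half-open intervals; intervals closer than gap_tolerance are
# fused. Keeps the max peak_error and the union of modalities per merged run.
merge_intervals <- function(iv, gap_tolerance = 0) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  starts <- iv$start[1]; ends <- iv$end[1]
  peaks <- iv$peak_error[1]
  mods <- iv$modality[1]; chans <- iv$channel_id[1]
  for (i in seq_len(nrow(iv))[-1]) {
    k <- length(starts)
    if (iv$start[i] <= ends[k] + gap_tolerance) {
      ends[k] <- max(ends[k], iv$end[i])
      peaks[k] <- max(peaks[k], iv$peak_error[i], na.rm = TRUE)
      mods[k] <- paste(sort(unique(c(strsplit(mods[k], "\\+")[[1]],
                                     strsplit(iv$modality[i], "\\+")[[1]]))),
                       collapse = "+")
      if (!identical(chans[k], iv$channel_id[i])) chans[k] <- NA_character_
    } else {
      starts <- c(starts, iv$start[i]); ends <- c(ends, iv$end[i])
      peaks <- c(peaks, iv$peak_error[i])
      mods <- c(mods, iv$modality[i]); chans <- c(chans, iv$channel_id[i])
    }
  }
  anomaly_intervals(starts, ends, peaks, mods, chans)
}

# Contiguous TRUE runs of a logical vector -> 0-based half-open intervals.
runs_to_intervals <- function(flag) {
  if (!any(flag)) return(cbind(start = numeric(0), end = numeric(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' @export
print.anomaly_intervals <- function(x, ...) {
  cat(sprintf("<anomaly_intervals> %d interval(s)\n", nrow(x)))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 20L), ...)
  invisible(x)
}
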