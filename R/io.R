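# Recording and label I/O.
#
# Two recording formats are supported: EDF (16-bit, 1-second data records; a
# minimal reader/writer is implemented here because no EDF package is
# available) and plain CSV (one column per channel, header row, sampling rate
# supplied by the caller). Labels travel as BED-like TSV or JSON.

EDF_DIG_MIN <- -32768L
EDF_DIG_MAX <- 32767L

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

#' Write a multichannel recording
#'
#' @param series a `channel_series` or list of them (equal length and fs).
#' @param path output file.
#' @param format `"edf"` or `"csv"` (default: inferred from extension).
#'
#' EDF stores samples as 16-bit integers scaled between the per-channel
#' physical min/max, in 1-second data records; the series length is padded to
#' a whole number of records (with the last value) if necessary, with a
#' warning. CSV stores full double precision.
#' @return `path`, invisibly.
#' @export
write_recording <- function(series, path, format = NULL) {
  if (inherits(series, "channel_series")) series <- list(series)
  if (!length(series) || !all(vapply(series, inherits, TRUE, "channel_series"))) {
    stop_param("'series' must be a channel_series or a list of them")
  }
  ns <- length(series)
  fs <- series[[1]]$fs
  n <- length(series[[1]]$values)
  if (!all(vapply(series, function(s) s$fs == fs, TRUE)) ||
      !all(vapply(series, function(s) length(s$values) == n, TRUE))) {
    stop_param("all channels must share sampling rate and length")
  }
  format <- tolower(format %||% tools::file_ext(path))
  if (format == "csv") {
    m <- do.call(cbind, lapply(series, function(s) s$values))
    colnames(m) <- vapply(series, function(s) s$channel_id, "")
    utils::write.csv(as.data.frame(m), path, row.names = FALSE)
    return(invisible(path))
  }
  if (format != "edf") stop_param("format must be 'edf' or 'csv'")
  if (fs != round(fs)) stop_param("EDF writer requires an integer sampling rate; use CSV")
  spr <- as.integer(fs)                      # samples per 1-second record
  nrec <- ceiling(n / spr)
  if (nrec * spr != n) {
    warning("padding final EDF record with the last sample value")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad_field("0", 8),
    pad_field(series[[1]]$patient_id, 80),
    pad_field("seegwatch recording", 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(hdr_bytes, 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field("1", 8), pad_field(ns, 4)
  ), con, eos = NULL)
  phys_min <- phys_max <- numeric(ns)
  for (i in seq_len(ns)) {
    v <- series[[i]]$values
    phys_min[i] <- min(v); phys_max[i] <- max(v)
    if (phys_min[i] == phys_max[i]) {        # EDF needs a nonzero range
      phys_min[i] <- phys_min[i] - 1; phys_max[i] <- phys_max[i] + 1
    }
  }
  fld <- function(f, width) writeChar(paste0(vapply(f, pad_field, "", width),
                                             collapse = ""), con, eos = NULL)
  fld(vapply(series, function(s) s$channel_id, ""), 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(phys_min, digits = 6, format = "g"), 8)
  fld(formatC(phys_max, digits = 6, format = "g"), 8)
  fld(rep(EDF_DIG_MIN, ns), 8)
  fld(rep(EDF_DIG_MAX, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(spr, ns), 8)
  fld(rep("", ns), 32)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    v <- series[[i]]$values
    if (length(v) < nrec * spr) v <- c(v, rep(v[length(v)], nrec * spr - length(v)))
    g <- (EDF_DIG_MAX - EDF_DIG_MIN) / (phys_max[i] - phys_min[i])
    dig[[i]] <- matrix(as.integer(round((v - phys_min[i]) * g) + EDF_DIG_MIN),
                       nrow = spr)
  }
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) writeBin(dig[[i]][, r], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a multichannel recording
#'
#' @param path file path (EDF or CSV).
#' @param format `"edf"`, `"csv"`, or `NULL` to infer from the extension.
#' @param fs sampling rate in Hz; required for CSV, ignored for EDF (read from
#'   the header).
#' @param patient_id provenance attached to each channel.
#' @return a list of `channel_series`, one per channel.
#' @export
read_recording <- function(path, format = NULL, fs = NULL, patient_id = "unknown") {
  if (!file.exists(path)) stop_data("no such file: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  if (format == "csv") {
    if (is.null(fs)) stop_param("reading a CSV recording requires 'fs'")
    raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    out <- vector("list", ncol(raw))
    for (j in seq_along(raw)) {
      v <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(is.na(v) & !is.na(raw[[j]]) & nzchar(raw[[j]]))
      if (length(bad) || anyNA(v)) {
        row <- if (length(bad)) bad[1] else which(is.na(v))[1]
        stop_data(sprintf("non-numeric value in CSV at row %d, column '%s'",
                          row, names(raw)[j]))
      }
      out[[j]] <- channel_series(v, fs, patient_id = patient_id,
                                 channel_id = names(raw)[j])
    }
    return(out)
  }
  if (format != "edf") stop_param("format must be 'edf' or 'csv'")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  version <- rd(8); pid <- rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(nrec)) stop_data("unreadable EDF header: ", path)
  sig_field <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- sig_field(16); sig_field(80); sig_field(8)
  pmin <- as.numeric(sig_field(8)); pmax <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8)); dmax <- as.numeric(sig_field(8))
  sig_field(80)
  spr <- as.integer(sig_field(8)); sig_field(32)
  total <- sum(spr)
  vals <- lapply(seq_len(ns), function(i) numeric(0))
  data <- readBin(con, "integer", n = total * nrec, size = 2L, signed = TRUE,
                  endian = "little")
  if (length(data) < total * nrec) stop_data("truncated EDF data section: ", path)
  offs <- c(0L, cumsum(spr))
  out <- vector("list", ns)
  for (i in seq_len(ns)) {
    idx <- unlist(lapply(seq_len(nrec) - 1L,
                         function(r) r * total + offs[i] + seq_len(spr[i])))
    g <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    out[[i]] <- channel_series((data[idx] - dmin[i]) * g + pmin[i],
                               fs = spr[i] / rec_dur,
                               patient_id = if (nzchar(pid)) pid else patient_id,
                               channel_id = labels[i])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || (is.character(a) && !nzchar(a))) b else a

#' Write event intervals
#'
#' @param labels an `event_labels` object.
#' @param path output file.
#' @param format `"tsv"` (BED-like: comment header carrying fs/source, then
#'   start/end columns in samples) or `"json"`. Inferred from extension when
#'   `NULL`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(labels, path, format = NULL) {
  if (!inherits(labels, "event_labels")) stop_param("'labels' must be event_labels")
  format <- tolower(format %||% tools::file_ext(path))
  if (format %in% c("tsv", "bed")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("#fs=%.10g", attr(labels, "fs")),
                 sprintf("#source=%s", attr(labels, "source")),
                 "start\tend"), con)
    if (nrow(labels) > 0L) {
      writeLines(sprintf("%.10g\t%.10g", labels$start, labels$end), con)
    }
    return(invisible(path))
  }
  if (format != "json") stop_param("format must be 'tsv' or 'json'")
  jsonlite::write_json(
    list(fs = attr(labels, "fs"), source = attr(labels, "source"),
         intervals = data.frame(start = labels$start, end = labels$end)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read event intervals
#'
#' @param path TSV or JSON file written by [write_intervals()] (or compatible).
#' @param strict if `TRUE`, malformed intervals raise an error instead of
#'   being normalised with a warning.
#' @return an `event_labels` object.
#' @export
read_labels <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  if (tolower(tools::file_ext(path)) == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    iv <- j$intervals
    return(event_labels(iv$start %||% numeric(), iv$end %||% numeric(),
                        fs = j$fs, source = j$source %||% "unknown",
                        strict = strict))
  }
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  fs <- as.numeric(sub("^#fs=", "", grep("^#fs=", meta, value = TRUE)[1]))
  src <- sub("^#source=", "", grep("^#source=", meta, value = TRUE)[1])
  if (is.na(fs)) stop_data("interval file lacks an #fs= header: ", path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) && grepl("^start", body[1])) body <- body[-1]
  if (!length(body)) return(event_labels(fs = fs, source = src))
  parts <- strsplit(body, "\t", fixed = TRUE)
  start <- as.numeric(vapply(parts, `[`, "", 1L))
  end <- as.numeric(vapply(parts, `[`, "", 2L))
  if (anyNA(start) || anyNA(end)) stop_data("malformed interval row in ", path)
  event_labels(start, end, fs = fs, source = if (is.na(src)) "unknown" else src,
               strict = strict)
}
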