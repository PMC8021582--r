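# Video frame handling. Frames are grayscale intensity grids in [0, 1],
# stored as an (H, W, N) array with a frame rate. Supported on-disk formats
# are PGM (ASCII "P2" and binary "P5") and CSV numeric grids; lexicographic
# filename order defines time.

#' Frame-sequence container
#'
#' @param frames numeric array `(H, W, N)` with intensities in `[0, 1]`, or a
#'   list of equal-shape matrices.
#' @param fps frame rate (> 0).
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps = 30) {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L) stop_param("frames have mixed shapes")
    frames <- array(unlist(frames), c(shapes[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L) stop_param("frames must be an (H, W, N) array")
  if (any(!is.finite(frames)) || min(frames) < 0 || max(frames) > 1) {
    stop_data("frame intensities must be finite and in [0, 1]")
  }
  assert_scalar_number(fps, "fps", lower = .Machine$double.eps)
  structure(list(frames = frames, fps = fps,
                 frame_shape = dim(frames)[1:2]),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frame(s) of %dx%d @ %g fps\n",
              dim(x$frames)[3], x$frame_shape[1], x$frame_shape[2], x$fps))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) dim(x$frames)[3]

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop_data("not a PGM file: ", path)
  # read header tokens (width, height, maxval), skipping comments
  tokens <- character(0)
  buf <- ""
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || !nzchar(ch)) stop_data("truncated PGM header: ", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[ \t\r\n]", ch)) {
      if (nzchar(buf)) { tokens <- c(tokens, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  n <- w * h
  if (magic == "P5") {
    raw_vals <- readBin(con, "integer", n = n, size = if (maxval < 256) 1L else 2L,
                        signed = FALSE, endian = "big")
    vals <- raw_vals
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop_data("truncated PGM data: ", path)
  t(matrix(vals, nrow = w, ncol = h)) / maxval   # row-major file order
}

#' Write a grayscale frame as ASCII PGM
#'
#' @param frame numeric matrix with values in `[0, 1]`.
#' @param path output path.
#' @param maxval integer grey-level ceiling (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(frame, path, maxval = 255L) {
  v <- round(pmin(pmax(frame, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(frame), nrow(frame)),
               as.character(maxval)), con)
  writeLines(apply(v, 1L, paste, collapse = " "), con)
  invisible(path)
}

# Bilinear resize of one frame.
resize_frame <- function(m, h, w) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr == h && nc == w) return(m)
  ri <- if (h == 1L) rep(1, h) else seq(1, nr, length.out = h)
  ci <- if (w == 1L) rep(1, w) else seq(1, nc, length.out = w)
  r0 <- pmin(floor(ri), nr - 1L); r1 <- r0 + 1L; fr <- ri - r0
  c0 <- pmin(floor(ci), nc - 1L); c1 <- c0 + 1L; fc <- ci - c0
  a <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
  a
}

#' Load frames from a directory
#'
#' Reads all `.pgm`/`.csv` frames in lexicographic filename order (which
#' defines time), converts to `[0, 1]` intensities, and optionally resizes and
#' temporally subsamples.
#'
#' @param directory directory containing frames.
#' @param target_size optional `c(height, width)` to resize to (bilinear).
#' @param stride temporal stride (keep every `stride`-th frame).
#' @param fps frame rate of the loaded sequence (after striding the effective
#'   rate is `fps / stride`, which is what gets recorded).
#' @param strict if `TRUE` an unreadable frame raises an error; otherwise it
#'   is skipped with a warning.
#' @return a [frame_sequence()].
#' @export
load_frames <- function(directory, target_size = NULL, stride = 1L, fps = 30,
                        strict = TRUE) {
  if (!dir.exists(directory)) stop_data("no such directory: ", directory)
  files <- sort(list.files(directory, pattern = "\\.(pgm|csv)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop_data("no .pgm or .csv frames in ", directory)
  files <- files[seq.int(1L, length(files), by = stride)]
  frames <- list()
  for (f in files) {
    m <- tryCatch({
      if (grepl("\\.csv$", f, ignore.case = TRUE)) {
        as.matrix(utils::read.csv(f, header = FALSE))
      } else read_pgm(f)
    }, error = function(e) e)
    if (inherits(m, "error")) {
      if (strict) stop_data("unreadable frame ", f, ": ", conditionMessage(m))
      warning("skipping unreadable frame ", f)
      next
    }
    m <- pmin(pmax(m, 0), 1)
    if (!is.null(target_size)) m <- resize_frame(m, target_size[1], target_size[2])
    frames[[length(frames) + 1L]] <- m
  }
  if (!length(frames)) stop_data("no readable frames in ", directory)
  frame_sequence(frames, fps = fps / stride)
}
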