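#' Envelope of an RF line
#'
#' Magnitude of the analytic signal (FFT-based Hilbert transform). The
#' envelope is non-negative and invariant to the carrier phase; for a
#' narrow-band Gabor pulse of amplitude `a` the envelope peak is within a
#' few percent of `a`.
#'
#' @param x RF sample vector.
#' @return Non-negative envelope vector of the same length.
#' @export
envelope <- function(x) {
  n <- length(x)
  if (n == 0) return(x)
  if (all(x == 0)) return(numeric(n))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE)) / n
}

#' Log compression to 8-bit pixels
#'
#' Maps an envelope to 0-255: 255 at the reference maximum, 0 at or below
#' `ref * 10^(-dynamic_range_db / 20)`, linear in dB in between. Order
#' preserving; an all-zero input maps to an all-zero image.
#'
#' @param env Envelope vector or matrix (non-negative).
#' @param dynamic_range_db Displayed dynamic range in dB (> 0).
#' @param ref Reference maximum; defaults to `max(env)`.
#' @return Pixel values in `[0, 255]` (rounded), same shape as `env`.
#' @export
log_compress <- function(env, dynamic_range_db = 50, ref = max(env)) {
  if (dynamic_range_db <= 0) stop("dynamic_range_db must be > 0", call. = FALSE)
  if (!is.finite(ref) || ref <= 0) return(env * 0)
  db <- 20 * log10(pmax(env, ref * 1e-30) / ref)
  px <- 255 * (1 + db / dynamic_range_db)
  round(pmin(pmax(px, 0), 255)) # px first: pmin/pmax keep its dim
}

#' Form a B-mode image from an RF frame
#'
#' Per-line envelope detection followed by log compression. Axial pixel
#' depth is rendered with the display speed of sound:
#' `depth = assumed_c * t / 2`.
#'
#' @param frame An `rf_frame` (see [acquire_frame()]).
#' @param dynamic_range_db Displayed dynamic range in dB.
#' @param ref Normalization reference; defaults to the frame's envelope
#'   maximum. Supply a common reference when comparing frames (e.g. echo-on
#'   vs echo-off).
#' @return An object of class `bmode_image` with `pixels`
#'   (lines x samples, 0-255), `envelope`, `depth_axis` (m), `line_x` (m)
#'   and `dynamic_range_db`.
#' @export
form_bmode <- function(frame, dynamic_range_db = 50, ref = NULL) {
  stopifnot(inherits(frame, "rf_frame"))
  env <- t(apply(frame$samples, 1, envelope))
  if (is.null(ref)) ref <- max(env)
  n <- ncol(env)
  structure(
    list(pixels = log_compress(env, dynamic_range_db, ref),
         envelope = env,
         depth_axis = frame$assumed_c * (seq_len(n) - 1) / frame$fs / 2,
         line_x = frame$line_x,
         dynamic_range_db = dynamic_range_db,
         ref = ref, fs = frame$fs, assumed_c = frame$assumed_c),
    class = "bmode_image"
  )
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("B-mode image: %d lines x %d samples, %g dB dynamic range, depth %.1f mm\n",
              nrow(x$pixels), ncol(x$pixels), x$dynamic_range_db,
              max(x$depth_axis) * 1e3))
  invisible(x)
}

#' @export
plot.bmode_image <- function(x, main = "B-mode", ...) {
  graphics::image(x$line_x * 1e3, x$depth_axis * 1e3, x$pixels,
                  col = grDevices::gray.colors(256, 0, 1), ylim = rev(range(x$depth_axis * 1e3)),
                  xlab = "lateral [mm]", ylab = "depth [mm]", main = main,
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Extract an M-mode image from a frame sequence
#'
#' One envelope column per frame, taken at a fixed A-line index. A device
#' blinking at 2 Hz viewed at 20 frames/s shows as alternating runs of 5
#' bright and 5 dark columns ("dashed line").
#'
#' @param frames List of `rf_frame`s.
#' @param line_index A-line to follow (1-based).
#' @return An object of class `mmode_image` with `columns`
#'   (samples x frames envelope matrix) and `frame_times` (s).
#' @export
extract_mmode <- function(frames, line_index) {
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  L <- nrow(frames[[1]]$samples)
  if (line_index < 1 || line_index > L) {
    stop("line_index outside the frame", call. = FALSE)
  }
  cols <- vapply(frames, function(fr) envelope(fr$samples[line_index, ]),
                 numeric(ncol(frames[[1]]$samples)))
  structure(
    list(columns = cols,
         frame_times = vapply(frames, function(fr) fr$frame_start, numeric(1)),
         line_index = line_index,
         depth_axis = frames[[1]]$assumed_c *
           (seq_len(nrow(cols)) - 1) / frames[[1]]$fs / 2),
    class = "mmode_image"
  )
}

#' @export
print.mmode_image <- function(x, ...) {
  cat(sprintf("M-mode image: line %d over %d frames\n",
              x$line_index, ncol(x$columns)))
  invisible(x)
}

#' @export
plot.mmode_image <- function(x, dynamic_range_db = 50, main = "M-mode", ...) {
  px <- log_compress(x$columns, dynamic_range_db)
  graphics::image(x$frame_times, x$depth_axis * 1e3, t(px),
                  col = grDevices::gray.colors(256, 0, 1),
                  ylim = rev(range(x$depth_axis * 1e3)),
                  xlab = "time [s]", ylab = "depth [mm]", main = main,
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Write an 8-bit image as plain PGM (P2)
#'
#' @param pixels Matrix of values in `[0, 255]`; rows become image columns
#'   (lines), i.e. the matrix is transposed into the usual image layout.
#' @param path Output path.
#' @param maxval Maximum gray value.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(pixels, path, maxval = 255) {
  m <- t(pixels) # width = lines, height = samples
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  apply(m, 1, function(row) writeLines(paste(round(row), collapse = " "), con))
  invisible(path)
}

#' Read a PGM image (plain P2 or binary P5)
#'
#' @param path Input path.
#' @return Matrix in the same orientation [write_pgm()] writes from
#'   (lines x samples).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file", call. = FALSE)
  vals <- integer(0)
  header <- integer(0)
  # read header tokens (width, height, maxval), skipping comments
  buf <- character(0)
  while (length(header) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") { repeat { c2 <- readChar(con, 1); if (c2 == "\n") break } ; next }
    if (grepl("\\s", ch)) {
      if (length(buf) > 0) { header <- c(header, as.integer(paste(buf, collapse = ""))); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  w <- header[1]; h <- header[2]; maxval <- header[3]
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", w * h))
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "\\s+")[[1]])[seq_len(w * h)]
  }
  matrix(vals, nrow = w, ncol = h) # back to lines x samples
}
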