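#' Build an optical-mapping recording object
#'
#' A recording couples a 3-D array of integer fluorescence intensities with
#' acquisition metadata. Frames are stored as `frames[row, col, frame]` with
#' row 1 at the top of the sensor; sample values must fit the stated bit
#' depth. On disk the same data live in the "OMR1" binary container (see
#' [write_recording()]).
#'
#' @param frames integer array with dim `c(height, width, n_frames)`, or a
#'   matrix (single frame).
#' @param frame_rate acquisition rate in frames per second.
#' @param bits_per_sample sample bit depth (1--16); values must lie in
#'   `[0, 2^bits_per_sample - 1]`.
#' @param pixel_size physical pixel pitch, mm per pixel.
#' @param format_version OMR1 container version (currently 1).
#'
#' @return An object of class `omr_recording`: a list with `header`
#'   (magic, format_version, width, height, frame_rate, bits_per_sample,
#'   n_frames, pixel_size) and `frames`.
#' @examples
#' rec <- recording(array(0L, c(4, 5, 10)), frame_rate = 977)
#' rec
#' @export
recording <- function(frames, frame_rate, bits_per_sample = 10L,
                      pixel_size = 0.035, format_version = 1L) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_argument("`frames` must be a height x width x n_frames array.")
  }
  header <- list(
    magic = "OMR1",
    format_version = as.integer(format_version),
    width = dim(frames)[[2L]],
    height = dim(frames)[[1L]],
    frame_rate = as.numeric(frame_rate),
    bits_per_sample = as.integer(bits_per_sample),
    n_frames = dim(frames)[[3L]],
    pixel_size = as.numeric(pixel_size)
  )
  storage.mode(frames) <- "integer"
  out <- structure(list(header = header, frames = frames),
                   class = "omr_recording")
  validate_recording(out)
  out
}

#' Validate a recording against its header invariants
#'
#' Checks metadata ranges, frame-array shape and that every sample lies in
#' the dynamic range promised by `bits_per_sample`.
#'
#' @param rec an `omr_recording`.
#' @return `rec`, invisibly; signals a validation error otherwise.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "omr_recording")) stop_validation("Not an `omr_recording` object.")
  h <- rec$header
  if (!identical(h$magic, "OMR1")) stop_validation("Header magic must be \"OMR1\".")
  if (h$width < 1L || h$height < 1L || h$n_frames < 1L) {
    stop_validation("width, height and n_frames must all be >= 1.")
  }
  if (!is.finite(h$frame_rate) || h$frame_rate <= 0) stop_validation("frame_rate must be > 0.")
  if (h$bits_per_sample < 1L || h$bits_per_sample > 16L) {
    stop_validation("bits_per_sample must be between 1 and 16.")
  }
  if (!is.finite(h$pixel_size) || h$pixel_size <= 0) stop_validation("pixel_size must be > 0.")
  if (!identical(dim(rec$frames), c(h$height, h$width, h$n_frames))) {
    stop_validation("frames shape is inconsistent with the header.")
  }
  rng <- range(rec$frames)
  if (anyNA(rng)) stop_validation("frames must not contain missing values.")
  if (rng[1L] < 0L || rng[2L] > 2^h$bits_per_sample - 1) {
    stop_validation(sprintf(
      "samples must lie in [0, %d] for %d-bit data; observed [%d, %d].",
      2^h$bits_per_sample - 1L, h$bits_per_sample, rng[1L], rng[2L]))
  }
  invisible(rec)
}

#' @export
print.omr_recording <- function(x, ...) {
  h <- x$header
  cat(sprintf("<omr_recording> %dx%d px, %d frames @ %.5g FPS (%.4g s)\n",
              h$height, h$width, h$n_frames, h$frame_rate,
              h$n_frames / h$frame_rate))
  cat(sprintf("  %d-bit samples, pixel size %.3g mm/px, intensity range [%d, %d]\n",
              h$bits_per_sample, h$pixel_size, min(x$frames), max(x$frames)))
  invisible(x)
}

OMR1_HEADER_BYTES <- 44L

write_uint32 <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "little")

read_uint32 <- function(con, what) {
  v <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(v) != 1L) stop_truncation(sprintf("file ends inside the header (%s).", what))
  if (v < 0) v <- v + 2^32
  v
}

#' Write a recording to an OMR1 binary file
#'
#' Serializes to the "OMR1 v1" container: a fixed 44-byte little-endian
#' header (`"OMR1"`, uint32 format_version, uint32 width, uint32 height,
#' float64 frame_rate, uint32 bits_per_sample, uint64 n_frames, float64
#' pixel_size) followed by `n_frames * height * width` uint16 samples in
#' frame-major, row-major order (column index varies fastest). Total file
#' size is therefore `44 + 2 * n_frames * height * width` bytes.
#'
#' @param rec an `omr_recording` satisfying [validate_recording()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  h <- rec$header
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw("OMR1"), con)
  write_uint32(con, h$format_version)
  write_uint32(con, h$width)
  write_uint32(con, h$height)
  writeBin(as.numeric(h$frame_rate), con, size = 8L, endian = "little")
  write_uint32(con, h$bits_per_sample)
  # uint64 n_frames as low/high uint32 words (recordings stay far below 2^32)
  write_uint32(con, h$n_frames)
  write_uint32(con, 0L)
  writeBin(as.numeric(h$pixel_size), con, size = 8L, endian = "little")
  # in-memory layout is (row, col, frame); file wants col fastest within frame
  samples <- aperm(rec$frames, c(2L, 1L, 3L))
  writeBin(as.vector(samples), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an OMR1 binary recording
#'
#' Parses the container written by [write_recording()]. The reader is
#' strict: a wrong magic tag raises a format error and a payload shorter
#' than the header promises raises a truncation error reporting expected
#' versus actual byte counts. Round trips are bit-exact.
#'
#' @param path path to an OMR1 file.
#' @return An `omr_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_argument(sprintf("File not found: %s", path))
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 4L))
  if (!identical(magic, "OMR1")) {
    stop_format(sprintf("Not an OMR1 recording: magic \"%s\" (expected \"OMR1\").", magic))
  }
  format_version <- read_uint32(con, "format_version")
  if (format_version != 1L) {
    stop_format(sprintf("Unsupported OMR1 format version %d.", format_version))
  }
  width <- read_uint32(con, "width")
  height <- read_uint32(con, "height")
  frame_rate <- readBin(con, "numeric", n = 1L, size = 8L, endian = "little")
  bits <- read_uint32(con, "bits_per_sample")
  n_lo <- read_uint32(con, "n_frames")
  n_hi <- read_uint32(con, "n_frames")
  if (n_hi != 0) stop_format("n_frames exceeds this reader's 2^32 frame limit.")
  pixel_size <- readBin(con, "numeric", n = 1L, size = 8L, endian = "little")
  if (length(frame_rate) != 1L || length(pixel_size) != 1L) {
    stop_truncation("file ends inside the header.")
  }
  n_samples <- n_lo * height * width
  payload <- readBin(con, "integer", n = n_samples, size = 2L,
                     signed = FALSE, endian = "little")
  if (length(payload) != n_samples) {
    expected <- OMR1_HEADER_BYTES + 2 * n_samples
    actual <- OMR1_HEADER_BYTES + 2 * length(payload)
    stop_truncation(sprintf(
      "Truncated payload: expected %.0f bytes, file provides %.0f.",
      expected, actual))
  }
  frames <- aperm(array(payload, dim = c(width, height, n_lo)), c(2L, 1L, 3L))
  recording(frames, frame_rate = frame_rate, bits_per_sample = bits,
            pixel_size = pixel_size, format_version = format_version)
}

#' Extract per-pixel time traces as a tidy table
#'
#' @param rec an `omr_recording`.
#' @param pixels a two-column matrix or data frame of 1-based
#'   `(row, col)` coordinates, or a list of length-2 vectors.
#' @return A tibble with one row per frame: `time_ms` (frame 1 at 0 ms,
#'   step `1000 / frame_rate`) and one `px_r{row}c{col}` column per
#'   requested pixel.
#' @examples
#' rec <- recording(array(seq_len(60), c(3, 4, 5)), frame_rate = 1000,
#'                  bits_per_sample = 16)
#' export_traces(rec, rbind(c(1, 1), c(3, 4)))
#' @export
export_traces <- function(rec, pixels) {
  validate_recording(rec)
  if (is.list(pixels) && !is.data.frame(pixels)) {
    pixels <- do.call(rbind, pixels)
  }
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L || ncol(pixels) != 2L) {
    stop_argument("`pixels` must be a non-empty set of (row, col) pairs.")
  }
  h <- rec$header
  bad <- pixels[, 1L] < 1L | pixels[, 1L] > h$height |
    pixels[, 2L] < 1L | pixels[, 2L] > h$width
  if (any(bad)) {
    stop_argument(sprintf("pixel (%d, %d) is out of bounds for %dx%d frames.",
                          pixels[which(bad)[1L], 1L], pixels[which(bad)[1L], 2L],
                          h$height, h$width))
  }
  out <- tibble::tibble(time_ms = (seq_len(h$n_frames) - 1) * 1000 / h$frame_rate)
  for (i in seq_len(nrow(pixels))) {
    nm <- sprintf("px_r%dc%d", pixels[i, 1L], pixels[i, 2L])
    out[[nm]] <- as.numeric(rec$frames[pixels[i, 1L], pixels[i, 2L], ])
  }
  out
}
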