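#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the uncompressed 16-bit mono recordings this
#' package writes and consumes. Samples are rescaled to `[-1, 1]`.
#'
#' @param path path to a `.wav` file.
#' @return A `waveform`: list with `samples` (numeric in `[-1, 1]`) and
#'   `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little") # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little") # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt[1] != 1L || bits != 16L)
        stop("only uncompressed 16-bit PCM WAV is supported")
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2L, size = 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(rate) || is.null(samples)) stop("malformed WAV: ", path)
  if (channels != 1L) stop("only mono WAV is supported")
  waveform(pmax(samples / 32767, -1), rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param w a `waveform` (see [waveform()]); samples are clamped to
#'   `[-1, 1]` before quantization.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  w <- as_waveform(w)
  x <- pmin(pmax(w$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little")   # PCM, mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")
  writeBin(as.integer(16), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Construct a waveform object
#'
#' @param samples numeric amplitude series, nominally in `[-1, 1]`.
#' @param rate sampling rate in Hz.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number")
  if (any(!is.finite(samples))) stop("waveform samples must be finite")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "waveform")
}

as_waveform <- function(w) {
  if (inherits(w, "waveform")) return(w)
  stop("expected a `waveform` object (see waveform())")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}
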