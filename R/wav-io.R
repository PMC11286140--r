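#' Waveform container
#'
#' A waveform is a list with `samples` (numeric vector, amplitudes in
#' \[-1, 1\]) and `rate` (sampling rate in Hz). All analysis functions in the
#' package accept and return this structure.
#'
#' @param samples numeric vector of amplitudes.
#' @param rate sampling rate in Hz (> 0).
#' @return An object of class `zr_wave`.
#' @export
waveform <- function(samples, rate) {
  stopifnot(is.numeric(samples), length(rate) == 1L, rate > 0)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "zr_wave")
}

#' @export
print.zr_wave <- function(x, ...) {
  cat(sprintf("<zr_wave: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wave a [waveform()].
#' @return length in seconds.
#' @export
wave_duration <- function(wave) length(wave$samples) / wave$rate

#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for mono 16-bit PCM, the format the study
#' recordings use. Samples are clipped to \[-1, 1\] and quantized to 16 bits.
#'
#' @param wave a [waveform()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "zr_wave"))
  x <- pmin(1, pmax(-1, wave$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  rate <- as.integer(round(wave$rate))
  byte_rate <- rate * 2L
  data_bytes <- n * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(byte_rate, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]. Skips unknown RIFF chunks; rejects
#' compressed, multi-channel or non-16-bit files.
#'
#' @param path WAV file path.
#' @return a [waveform()] with samples scaled to \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L || bits != 16L)
        stop("only mono 16-bit PCM WAV supported: ", path)
      if (sz > 16) readBin(con, "raw", n = sz - 16L)
    } else if (id == "data") {
      if (is.null(rate)) stop("data chunk before fmt in ", path)
      pcm <- readBin(con, "integer", n = sz %/% 2L, size = 2,
                     signed = TRUE, endian = "little")
      return(waveform(pcm / 32768, rate))
    } else {
      readBin(con, "raw", n = sz + (sz %% 2L))
    }
  }
}
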