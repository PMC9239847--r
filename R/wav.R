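## Minimal RIFF/WAVE I/O (mono, PCM16 or IEEE float32) for the audio feature
## extractors; written in-package because no WAV reader ships with the
## environment's R stack.

#' Read a mono WAV file
#'
#' Supports PCM 16-bit and IEEE float 32-bit.  Multichannel files are
#' averaged to mono.
#'
#' @param path file path.
#' @return list with `samples` (numeric, in [-1, 1] for PCM) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file", call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(raw[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("read_wav: data chunk before fmt chunk", call. = FALSE)
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", sz / 2, 2, endian = "little") / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", sz / 4, 4, endian = "little")
      } else {
        stop("read_wav: unsupported encoding (need PCM16 or float32)", call. = FALSE)
      }
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("read_wav: no data chunk found", call. = FALSE)
  if (fmt$n_channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = fmt$n_channels))
  }
  list(samples = as.numeric(samples), rate = fmt$sample_rate)
}

#' Write a mono WAV file (PCM 16-bit)
#'
#' @param samples numeric vector in [-1, 1]; values outside are clipped.
#' @param rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  pcm <- as.integer(round(clip(samples, -1, 1) * 32767))
  data_sz <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")              # PCM, mono
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, 4, endian = "little")  # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")             # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
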