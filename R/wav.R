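#' Minimal RIFF/WAVE audio I/O
#'
#' The package stores synthetic calls as ordinary RIFF WAVE files so that
#' corpora can be inspected with any audio tool. Reading supports mono or
#' multi-channel PCM at 16 or 24 bits and IEEE float at 32 bits; writing
#' always produces 16-bit PCM mono, the format of the field recordings the
#' pipeline emulates.
#'
#' @name wav-io
NULL

#' Construct an audio clip
#'
#' An `audio_clip` is a mono sampled waveform with its sample rate; it is the
#' unit of synthesis and feature extraction. Samples are dimensionless
#' amplitudes in `[-1, 1]`.
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @return An object of class `audio_clip` with elements `samples` and
#'   `sample_rate`.
#' @export
audio_clip <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0)
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("audio_clip: %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds (`length(samples) / sample_rate`).
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' Write a mono waveform as 16-bit PCM WAV
#'
#' Samples outside `[-1, 1]` are an error (the synthesizer never produces
#' them). Amplitudes scale by 2^15 (clamped to the 16-bit range), matching
#' the divisor used on read so a write/read round trip is transparent to
#' quantization precision.
#'
#' @param clip An `audio_clip`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  if (max(abs(x)) > 1 + 1e-9) stop("samples exceed [-1, 1]; refusing to clip")
  pcm <- as.integer(pmin(round(pmax(pmin(x, 1), -1) * 32768), 32767))
  n <- length(pcm)
  fs <- as.integer(round(clip$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")       # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")   # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a WAV file as a mono audio clip
#'
#' Multi-channel input is averaged to mono. Integer PCM is rescaled to
#' `[-1, 1]`; 32-bit float data is taken as-is.
#'
#' @param path Path to a RIFF/WAVE file.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(body[1:2], "integer", 1, size = 2, endian = "little"),
        channels  = readBin(body[3:4], "integer", 1, size = 2, endian = "little"),
        rate      = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits      = readBin(body[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (length(data_raw) < sz) stop("truncated WAV data chunk: ", path)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)
  bytes_per <- fmt$bits %/% 8L
  n_frames <- length(data_raw) %/% (bytes_per * fmt$channels)
  if (n_frames == 0L) stop("empty audio data: ", path)
  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n_frames * fmt$channels,
                 size = 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(3L * n_frames * fmt$channels)]),
                nrow = 3L)
    v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", n_frames * fmt$channels,
                 size = 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit): %s",
                 fmt$format, fmt$bits, path))
  }
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_clip(x, fmt$rate)
}
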