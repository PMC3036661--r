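#' Acoustic heart-sound signal
#'
#' Container for a sampled heart-sound recording. Samples are dimensionless
#' amplitudes; after [normalize_signal()] the maximum absolute amplitude is
#' exactly 1, which makes recordings from different subjects (quieter or
#' louder hearts) comparable.
#'
#' @param samples Numeric vector of amplitudes. Must be finite.
#' @param rate Sampling rate in Hz (samples per second), positive scalar.
#' @param source_label Free-text provenance label, e.g. `"stethoscope"` or
#'   `"hydrophone"`.
#'
#' @return An object of class `acoustic_signal`: a list with elements
#'   `samples`, `rate` and `source_label`.
#' @seealso [read_wav()], [normalize_signal()]
#' @export
#' @examples
#' s <- acoustic_signal(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), rate = 1000)
#' s
acoustic_signal <- function(samples, rate, source_label = "unknown") {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         source_label = as.character(source_label)[1L]),
    class = "acoustic_signal"
  )
}

#' @export
print.acoustic_signal <- function(x, ...) {
  cat(sprintf("<acoustic_signal> %d samples @ %g Hz (%.3f s), source: %s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              x$source_label))
  cat(sprintf("  amplitude range [%.4g, %.4g]\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.acoustic_signal <- function(x) length(x$samples)

#' Peak-normalize a signal
#'
#' Divides every sample by the maximum absolute amplitude so that the output
#' peaks at exactly 1 in magnitude. Normalization is applied at the start of
#' the analysis pipeline so that energy percentages are comparable across
#' recordings; it preserves the waveform shape. The operation is idempotent.
#'
#' @param signal An [acoustic_signal()].
#' @return A normalized `acoustic_signal` with `max(abs(samples)) == 1`.
#' @export
normalize_signal <- function(signal) {
  stopifnot(inherits(signal, "acoustic_signal"))
  m <- max(abs(signal$samples))
  if (m == 0) {
    stop("cannot normalize an all-zero (silent) signal", call. = FALSE)
  }
  signal$samples <- signal$samples / m
  signal
}

# ---- RIFF/WAVE PCM I/O ------------------------------------------------------
# Hand-rolled minimal RIFF parser: integer PCM only (format tag 1), 1-2
# channels, 8/16/24/32 bits. Full-scale divisor is 2^(bits-1) (symmetric
# negative convention), so a 16-bit sample 32767 maps to 32767/32768.

.wav_read_chunks <- function(raw) {
  if (length(raw) < 44L ||
      rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "WAVE") {
    stop("not a RIFF/WAVE file", call. = FALSE)
  }
  chunks <- list()
  pos <- 13L
  n <- length(raw)
  while (pos + 8L <= n + 1L) {
    id <- rawToChar(raw[pos:(pos + 3L)])
    size <- sum(as.integer(raw[(pos + 4L):(pos + 7L)]) * c(1, 256, 65536, 16777216))
    data_start <- pos + 8L
    data_end <- min(data_start + size - 1L, n)
    chunks[[id]] <- raw[data_start:data_end]
    pos <- data_start + size + (size %% 2L)  # chunks are word-aligned
  }
  chunks
}

.wav_u16 <- function(raw, off) sum(as.integer(raw[off + 0:1]) * c(1, 256))
.wav_u32 <- function(raw, off) sum(as.integer(raw[off + 0:3]) * c(1, 256, 65536, 16777216))

#' Read a PCM WAV recording
#'
#' Reads an integer PCM RIFF/WAVE file (8, 16, 24 or 32 bit, mono or stereo)
#' and rescales samples to `[-1, 1)` using the full-scale divisor
#' `2^(bits - 1)`. Stereo recordings (e.g. a stethoscope and hydrophone
#' captured through a Y-adapter on one sound card) are handled by extracting
#' one channel; no cross-channel processing is done.
#'
#' @param path Path to a WAV file.
#' @param channel Channel to extract: 1 (first/left), 2 (second/right), or
#'   `"mono-mix"` to average the channels.
#' @param source_label Label stored on the returned signal; defaults to the
#'   file name.
#' @return An [acoustic_signal()].
#' @export
read_wav <- function(path, channel = 1L, source_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, what = "raw", n = file.size(path))
  chunks <- .wav_read_chunks(raw)
  fmt <- chunks[["fmt "]]
  if (is.null(fmt) || is.null(chunks[["data"]])) {
    stop("WAV file is missing fmt/data chunks", call. = FALSE)
  }
  audio_format <- .wav_u16(fmt, 1L)
  n_channels <- .wav_u16(fmt, 3L)
  rate <- .wav_u32(fmt, 5L)
  bits <- .wav_u16(fmt, 15L)
  if (audio_format != 1L) {
    stop("unsupported WAV encoding (format tag ", audio_format,
         "); only integer PCM is supported", call. = FALSE)
  }
  if (!n_channels %in% 1:2) {
    stop("only mono or stereo WAV supported (got ", n_channels, " channels)",
         call. = FALSE)
  }
  if (!bits %in% c(8L, 16L, 24L, 32L)) {
    stop("unsupported bit depth: ", bits, call. = FALSE)
  }

  data <- chunks[["data"]]
  x <- switch(as.character(bits),
    "8" = as.numeric(as.integer(data)) - 128,
    "16" = as.numeric(readBin(data, "integer", n = length(data) %/% 2L,
                              size = 2L, signed = TRUE, endian = "little")),
    "24" = {
      m <- length(data) %/% 3L
      b <- matrix(as.numeric(data[seq_len(3L * m)]), nrow = 3L)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      ifelse(v >= 8388608, v - 16777216, v)
    },
    "32" = as.numeric(readBin(data, "integer", n = length(data) %/% 4L,
                              size = 4L, signed = TRUE, endian = "little"))
  )
  full_scale <- 2^(bits - 1L)
  x <- x / full_scale

  if (n_channels == 2L) {
    x <- matrix(x, nrow = 2L)
    if (identical(channel, "mono-mix")) {
      x <- colMeans(x)
    } else {
      channel <- as.integer(channel)
      if (!channel %in% 1:2) {
        stop("channel index out of range (stereo file has channels 1 and 2)",
             call. = FALSE)
      }
      x <- x[channel, ]
    }
  } else if (!identical(channel, "mono-mix") && as.integer(channel) != 1L) {
    stop("channel index out of range for a mono file", call. = FALSE)
  }
  acoustic_signal(x, rate = rate, source_label = source_label)
}

#' Write a signal as 16-bit PCM WAV
#'
#' Quantizes with the same symmetric full-scale convention as [read_wav()]
#' (divisor 32768), so reading a file written from 16-bit data round-trips
#' bit-exactly.
#'
#' @param signal An [acoustic_signal()] with samples in `[-1, 1)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "acoustic_signal"))
  ints <- as.integer(pmax(-32768, pmin(32767, round(signal$samples * 32768))))
  n_bytes <- 2L * length(ints)
  con <- file(path, "wb")
  on.exit(close(con))
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); u32(36L + n_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); u32(16L)
  u16(1L); u16(1L)                       # PCM, mono
  u32(round(signal$rate))
  u32(round(signal$rate) * 2L)           # byte rate
  u16(2L); u16(16L)                      # block align, bits
  writeChar("data", con, eos = NULL); u32(n_bytes)
  writeBin(ints, con, size = 2L, endian = "little")
  invisible(path)
}
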