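# Shared fixture builders. Everything is generated in code; no binary files.

# ensemble of hb random beats of length n (iid noise rows)
random_ensemble <- function(hb, n, seed = 1, rate = 1000) {
  set.seed(seed)
  beat_ensemble(matrix(rnorm(hb * n), nrow = hb), rate = rate)
}

# ensemble built from a common template plus per-beat noise
template_ensemble <- function(hb, n, noise_sd = 0.1, seed = 1, rate = 1000) {
  set.seed(seed)
  t <- seq_len(n) / n
  tmpl <- sin(2 * pi * 3 * t) * exp(-((t - 0.15) / 0.08)^2) +
    0.5 * sin(2 * pi * 5 * t) * exp(-((t - 0.55) / 0.08)^2)
  rows <- t(vapply(seq_len(hb), function(m) tmpl + rnorm(n, 0, noise_sd),
                   numeric(n)))
  beat_ensemble(rows, rate = rate)
}

# a smooth beat with a dominant S1-like peak near the start and an S2-like
# peak later; delayed copies stay recoverable by peak alignment
peaked_beat <- function(n = 400, s1_pos = 0.12, s2_pos = 0.6) {
  i <- seq_len(n) / n
  exp(-((i - s1_pos) / 0.03)^2) * sin(2 * pi * 12 * i) +
    0.5 * exp(-((i - s2_pos) / 0.03)^2) * sin(2 * pi * 15 * i)
}

# integer right (s>0) / left (s<0) shift with zero fill, fixed length
delay_beat <- function(beat, s) {
  n <- length(beat)
  if (s >= 0) c(rep(0, s), beat[seq_len(n - s)])
  else c(beat[(-s + 1):n], rep(0, -s))
}

# minimal in-code 16-bit mono WAV writer independent of the package reader,
# used to validate read_wav against a second implementation of the format
reference_wav_16 <- function(path, ints, rate, channels = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); u32(36L + 2L * length(ints))
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); u32(16L)
  u16(1L); u16(channels); u32(rate); u32(rate * 2L * channels)
  u16(2L * channels); u16(16L)
  writeChar("data", con, eos = NULL); u32(2L * length(ints))
  writeBin(as.integer(ints), con, size = 2L, endian = "little")
  path
}

extdata <- function(name) {
  system.file("extdata", name, package = "pcgenergy", mustWork = TRUE)
}
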