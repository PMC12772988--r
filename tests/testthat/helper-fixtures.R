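# small constructed inputs shared across tests

sine_clip <- function(freq_hz, duration_s = 1, sample_rate = 8000,
                      amplitude = 0.5) {
  t <- seq_len(round(duration_s * sample_rate)) / sample_rate
  audio_clip(amplitude * sin(2 * pi * freq_hz * t), sample_rate)
}

# minimal 16-bit PCM stereo WAV writer, independent of the package's writer
write_stereo_wav <- function(left, right, sample_rate, path) {
  q <- as.integer(round(rbind(left, right) * 32767))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate) * 4L, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(as.integer(q), con, size = 2L, endian = "little")
  path
}

# uniform grayscale frames at the video target size
uniform_frames <- function(n, value, h = 350, w = 600) {
  lapply(seq_len(n), function(i) matrix(value, h, w))
}

# independent single-channel evaluation of the periodicity sum at one lag
naive_periodicity <- function(x, l) {
  xc <- x - mean(x)
  n <- length(xc)
  sum(xc[1:(n - l)] * xc[(l + 1):n]) / (n - l)
}
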