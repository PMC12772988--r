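#' Audio clip container
#'
#' A mono audio signal with its sample rate. Samples are dimensionless
#' amplitudes, nominally in `[-1, 1]` for material read from PCM WAV.
#'
#' @param samples Numeric vector of finite sample values.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @return An object of class `audio_clip` with elements `samples` and
#'   `sample_rate`.
#' @export
audio_clip <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  sample_rate <- as.numeric(sample_rate)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a positive scalar")
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE files with 16- or 24-bit integer PCM encoding. Stereo (or
#' higher channel count) material is down-mixed to mono by the channel mean;
#' the modeled recording setup is a single lavalier microphone, so mono is the
#' canonical case.
#'
#' @param path Path to a WAV file.
#' @return An [audio_clip()] with samples scaled to `[-1, 1]` and the file's
#'   native sample rate.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      audio_format <- readBin(fmt_raw[1:2], "integer", 1L, size = 2L,
                              endian = "little", signed = FALSE)
      n_channels <- readBin(fmt_raw[3:4], "integer", 1L, size = 2L,
                            endian = "little", signed = FALSE)
      sample_rate <- readBin(fmt_raw[5:8], "integer", 1L, size = 4L,
                             endian = "little")
      bits <- readBin(fmt_raw[15:16], "integer", 1L, size = 2L,
                      endian = "little", signed = FALSE)
      fmt <- list(format = audio_format, channels = n_channels,
                  rate = sample_rate, bits = bits)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)
  if (fmt$format != 1L)
    stop("unsupported WAV encoding (only integer PCM is supported): format tag ",
         fmt$format)
  bytes_per <- fmt$bits %/% 8L
  if (!fmt$bits %in% c(16L, 24L))
    stop("unsupported bit depth: ", fmt$bits, " (only 16/24-bit PCM)")
  n <- length(data_raw) %/% bytes_per
  if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n, size = 2L, endian = "little")
    x <- x / 32768
  } else {
    m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
    x <- m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ]
    x <- ifelse(x >= 8388608, x - 16777216, x) / 8388608
  }
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_clip(x, fmt$rate)
}

#' Write a PCM WAV file
#'
#' Writes mono 16-bit integer PCM. Samples are clipped to `[-1, 1]` and
#' quantized by rounding to the nearest 16-bit level.
#'
#' @param clip An [audio_clip()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(1, pmax(-1, clip$samples))
  q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")                 # PCM
  writeBin(1L, con, size = 2L, endian = "little")                 # mono
  sr <- as.integer(round(clip$sample_rate))
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(sr * 2L, con, size = 4L, endian = "little")            # byte rate
  writeBin(2L, con, size = 2L, endian = "little")                 # block align
  writeBin(16L, con, size = 2L, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}

#' Resample an audio clip
#'
#' Polyphase resampling via [signal::resample()] at the rational rate
#' `p/q = target_hz/clip$sample_rate` (reduced by their GCD). Duration is
#' preserved to within one sample period.
#'
#' @param clip An [audio_clip()].
#' @param target_hz Target sampling rate in Hz.
#' @return An [audio_clip()] at `target_hz`.
#' @export
resample_audio <- function(clip, target_hz) {
  stopifnot(inherits(clip, "audio_clip"), target_hz > 0)
  if (isTRUE(all.equal(clip$sample_rate, target_hz))) {
    return(audio_clip(clip$samples, target_hz))
  }
  r <- .rational_ratio(target_hz, clip$sample_rate)
  y <- signal::resample(clip$samples, p = r[1L], q = r[2L])
  n_out <- ceiling(length(clip$samples) * r[1L] / r[2L])
  y <- y[seq_len(min(n_out, length(y)))]
  audio_clip(y, target_hz)
}

.rational_ratio <- function(a, b, tol = 1e-9) {
  # integer rates are the expected case; fall back to a rounded scale
  if (abs(a - round(a)) < tol && abs(b - round(b)) < tol) {
    a <- round(a); b <- round(b)
    g <- .gcd(a, b)
    c(a %/% g, b %/% g)
  } else {
    f <- 1e6
    g <- .gcd(round(a * f), round(b * f))
    c(round(a * f) %/% g, round(b * f) %/% g)
  }
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Breath-phase annotation track
#'
#' Timed inspiration/expiration segments, as produced by human annotation
#' (e.g., ELAN exports). Segments are validated and sorted by start time;
#' same-phase segments must not overlap.
#'
#' @param phase Character vector, each `"inspiration"` or `"expiration"`.
#' @param start,end Segment bounds in seconds, `start < end` elementwise.
#' @return An object of class `annotation_track`: a data.frame with columns
#'   `phase`, `start`, `end`, sorted by `start`.
#' @export
annotation_track <- function(phase = character(), start = numeric(),
                             end = numeric()) {
  phase <- as.character(phase)
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(phase) == length(start), length(start) == length(end))
  bad <- setdiff(unique(phase), c("inspiration", "expiration"))
  if (length(bad)) stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  if (any(start >= end)) stop("each segment must have start < end")
  o <- order(start, end)
  d <- data.frame(phase = phase[o], start = start[o], end = end[o],
                  stringsAsFactors = FALSE)
  for (ph in c("inspiration", "expiration")) {
    s <- d[d$phase == ph, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)] - 1e-12))
      stop("overlapping ", ph, " segments")
  }
  class(d) <- c("annotation_track", "data.frame")
  d
}

#' Read breath annotations from CSV
#'
#' Expects the dialect `label,start,end` (header row; seconds as decimals).
#' Raw ELAN tab-separated exports can be adapted with `sep = "\t"`.
#'
#' @param path CSV file path.
#' @param sep Field separator (default comma).
#' @return An [annotation_track()], sorted and validated. An empty file (header
#'   only) yields an empty track.
#' @export
read_annotations <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0L) return(annotation_track())
  need <- c("label", "start", "end")
  if (!all(need %in% names(d)))
    stop("annotation CSV must have columns label,start,end")
  annotation_track(d$label, d$start, d$end)
}

#' Write breath annotations to CSV
#'
#' Inverse of [read_annotations()]; round-trips segment tuples exactly at
#' full double precision.
#'
#' @param track An [annotation_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  d <- data.frame(label = track$phase,
                  start = format(track$start, digits = 17, scientific = FALSE,
                                 trim = TRUE),
                  end = format(track$end, digits = 17, scientific = FALSE,
                               trim = TRUE))
  utils::write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Frame feature matrix
#'
#' The channels-by-frames feature representation shared by every estimator:
#' 80 log-Mel channels for audio, 84 grid-cell intensity channels for video,
#' or their 164-channel fusion.
#'
#' @param values Numeric matrix, channels x frames, all finite.
#' @param frame_rate Frames per second (positive).
#' @param modality One of `"audio"`, `"video"`, `"fused"`.
#' @return An object of class `frame_features`.
#' @export
frame_features <- function(values, frame_rate,
                           modality = c("audio", "video", "fused")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("feature values must be finite")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  structure(list(values = values, frame_rate = as.numeric(frame_rate),
                 modality = modality),
            class = "frame_features")
}

#' @export
print.frame_features <- function(x, ...) {
  cat(sprintf("<frame_features> %s: %d channels x %d frames @ %.3f frames/s\n",
              x$modality, nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

#' Fuse audio and video feature matrices
#'
#' Concatenates along the channel axis (audio channels first), truncating to
#' the shorter frame count. Frame rates must agree to within 0.1 frames/s
#' (the audio feature rate 8000/267 = 29.96 and the video rate 29.9 are
#' treated as synchronized; streams are assumed to share t = 0).
#'
#' @param a Audio [frame_features()].
#' @param v Video [frame_features()].
#' @return A fused [frame_features()] with `a`'s frame rate.
#' @export
align_modalities <- function(a, v) {
  stopifnot(inherits(a, "frame_features"), inherits(v, "frame_features"))
  if (abs(a$frame_rate - v$frame_rate) > 0.1)
    stop(sprintf("incompatible frame rates: %.3f vs %.3f",
                 a$frame_rate, v$frame_rate))
  n <- min(ncol(a$values), ncol(v$values))
  frame_features(rbind(a$values[, seq_len(n), drop = FALSE],
                       v$values[, seq_len(n), drop = FALSE]),
                 a$frame_rate, "fused")
}

#' Serialize a feature matrix
#'
#' Writes a flat little-endian float64 binary (`<path>.bin`, column-major,
#' channels varying fastest) plus a JSON sidecar (`<path>.json`) with the
#' channel count, frame count, frame rate and modality. The pair round-trips
#' losslessly at 64-bit precision.
#'
#' @param x A [frame_features()].
#' @param path Output path stem (extensions are appended).
#' @return `path`, invisibly.
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "frame_features"))
  bin <- paste0(path, ".bin")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x$values), con, size = 8L, endian = "little")
  meta <- list(channels = nrow(x$values), frames = ncol(x$values),
               frame_rate = x$frame_rate, modality = x$modality,
               dtype = "float64-le", order = "column-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a serialized feature matrix
#'
#' @param path Path stem as given to [write_features()].
#' @return A [frame_features()].
#' @export
read_features <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$channels * meta$frames
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n, size = 8L, endian = "little")
  frame_features(matrix(v, nrow = meta$channels), meta$frame_rate,
                 meta$modality)
}
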