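#' Video grid feature configuration
#'
#' The standard configuration crops to a chest region of interest, resizes to
#' 350 x 600 pixels and averages intensity over a 7 x 12 grid of 50 x 50
#' windows, one feature channel per cell. The grid must tile the target size
#' exactly.
#'
#' @param roi `"full"` or an integer vector `c(x0, y0, x1, y1)` of pixel
#'   bounds (1-based, inclusive; x = column, y = row). The chest box would
#'   normally come from a pose detector on the first frame; here it is plain
#'   configuration.
#' @param target_size `c(height, width)` after resize; default `c(350, 600)`.
#' @param window `c(height, width)` of each averaging cell; default `c(50, 50)`.
#' @return A `video_feature_config` list with the derived grid dimensions.
#' @export
video_feature_config <- function(roi = "full", target_size = c(350L, 600L),
                                 window = c(50L, 50L)) {
  if (any(target_size %% window != 0))
    stop("target_size must be divisible by window")
  grid <- target_size %/% window
  structure(list(roi = roi, target_size = as.integer(target_size),
                 window = as.integer(window), grid = as.integer(grid)),
            class = "video_feature_config")
}

# BT.601 luma from an H x W x 3 array; matrices pass through unchanged.
.to_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3L && dim(frame)[3L] == 3L) {
    return(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L])
  }
  stop("frames must be grayscale matrices or H x W x 3 arrays")
}

#' Video grid features
#'
#' Converts a sequence of frames into the 84-channel grid feature matrix:
#' each frame is cropped to the ROI, converted to grayscale (BT.601 weights),
#' bilinearly resized to the target size, and averaged over each grid cell.
#' Channels are ordered row-major over the grid (channel 1 = top-left cell,
#' channel 2 = its right neighbour, ...), so with the default 7 x 12 grid,
#' cell (r, c) (1-based) maps to channel `(r - 1) * 12 + c`.
#'
#' @param frames List of frames (numeric matrices, or H x W x 3 arrays), all
#'   the same shape; or a 3-D array H x W x T of grayscale frames.
#' @param frame_rate Frames per second.
#' @param cfg A [video_feature_config()].
#' @return A [frame_features()] of modality `"video"`, `prod(grid)` x T.
#' @export
video_grid_features <- function(frames, frame_rate,
                                cfg = video_feature_config()) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3L]), function(t) frames[, , t])
  }
  if (!is.list(frames) || length(frames) == 0L)
    stop("empty frame sequence")
  gh <- cfg$grid[1L]; gw <- cfg$grid[2L]
  th <- cfg$target_size[1L]; tw <- cfg$target_size[2L]
  # cell averaging as two aggregation products: (gh x th) %*% img %*% (tw x gw)
  A <- matrix(0, gh, th)
  for (r in seq_len(gh)) A[r, ((r - 1L) * cfg$window[1L] + 1L):(r * cfg$window[1L])] <- 1
  B <- matrix(0, tw, gw)
  for (c in seq_len(gw)) B[((c - 1L) * cfg$window[2L] + 1L):(c * cfg$window[2L]), c] <- 1
  denom <- prod(cfg$window)

  shape <- dim(.to_gray(frames[[1L]]))
  out <- matrix(0, gh * gw, length(frames))
  for (t in seq_along(frames)) {
    g <- .to_gray(frames[[t]])
    if (!identical(dim(g), shape)) stop("all frames must share one shape")
    if (!identical(cfg$roi, "full")) {
      b <- cfg$roi
      g <- g[b[2L]:b[4L], b[1L]:b[3L], drop = FALSE]
    }
    if (!identical(dim(g), c(th, tw))) {
      g <- EBImage::resize(g, w = th, h = tw, filter = "bilinear")
    }
    cells <- A %*% g %*% B / denom          # gh x gw of cell means
    out[, t] <- as.numeric(t(cells))        # row-major channel order
  }
  frame_features(out, frame_rate, "video")
}

#' Audio feature configuration
#'
#' Log-Mel spectrogram settings. The defaults (8 kHz, 512-sample window,
#' 267-sample hop, 80 Mel bins) produce frames at 8000/267 = 29.96 frames/s,
#' matching the 29.9 frames/s video rate to within 0.1.
#'
#' @param sample_rate Expected sample rate in Hz.
#' @param win_length STFT window length in samples.
#' @param hop_length STFT hop in samples (must be < `win_length`).
#' @param n_mels Number of Mel bands.
#' @param log_floor Additive floor inside the log.
#' @param f_min,f_max Mel filterbank frequency range in Hz; `f_max = NULL`
#'   means Nyquist.
#' @return An `audio_feature_config` list.
#' @export
audio_feature_config <- function(sample_rate = 8000, win_length = 512L,
                                 hop_length = 267L, n_mels = 80L,
                                 log_floor = 1e-10, f_min = 0, f_max = NULL) {
  if (hop_length >= win_length) stop("hop_length must be < win_length")
  if (n_mels <= 0) stop("n_mels must be positive")
  if (is.null(f_max)) f_max <- sample_rate / 2
  structure(list(sample_rate = sample_rate, win_length = as.integer(win_length),
                 hop_length = as.integer(hop_length), n_mels = as.integer(n_mels),
                 log_floor = log_floor, f_min = f_min, f_max = f_max),
            class = "audio_feature_config")
}

.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)   # HTK scale
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# n_mels x (n_fft/2 + 1) triangular filterbank on FFT bin frequencies.
.mel_filterbank <- function(n_mels, n_fft, sample_rate, f_min, f_max) {
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- seq(0, sample_rate / 2, length.out = n_bins)
  edges <- .mel_to_hz(seq(.hz_to_mel(f_min), .hz_to_mel(f_max),
                          length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    dn <- (hi - bin_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Log-Mel spectrogram
#'
#' Short-time Fourier transform with a periodic Hann window, centre padding
#' (reflection), power spectrum (|.|^2), an HTK-scale triangular Mel
#' filterbank, and `log(mel_power + log_floor)`. Frame `t` (1-based) is
#' centred on sample `(t - 1) * hop_length + 1`, giving
#' `T = 1 + floor(n_samples / hop_length)` frames.
#'
#' @param clip An [audio_clip()]; its sample rate must equal
#'   `cfg$sample_rate` (resample first with [resample_audio()]).
#' @param cfg An [audio_feature_config()].
#' @return A [frame_features()] of modality `"audio"`, `n_mels` x T, with
#'   `frame_rate = sample_rate / hop_length`.
#' @export
log_mel_spectrogram <- function(clip, cfg = audio_feature_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  if (abs(clip$sample_rate - cfg$sample_rate) > 1e-6)
    stop("clip sample rate ", clip$sample_rate, " != config sample rate ",
         cfg$sample_rate, "; resample first")
  x <- clip$samples
  n_fft <- cfg$win_length
  if (length(x) < n_fft) stop("clip shorter than one analysis window")
  half <- n_fft %/% 2L
  # reflect-pad half a window on each side (librosa-style centre padding)
  x_pad <- c(rev(x[2L:(half + 1L)]), x, rev(x[(length(x) - half):(length(x) - 1L)]))
  n_frames <- 1L + length(x) %/% cfg$hop_length
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * cfg$hop_length, "+")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_fft) - 1L) / n_fft)  # periodic Hann
  framed <- matrix(x_pad[idx], nrow = n_fft) * w
  spec <- stats::mvfft(framed)[seq_len(half + 1L), , drop = FALSE]
  power <- Re(spec)^2 + Im(spec)^2
  fb <- .mel_filterbank(cfg$n_mels, n_fft, cfg$sample_rate, cfg$f_min, cfg$f_max)
  frame_features(log(fb %*% power + cfg$log_floor),
                 cfg$sample_rate / cfg$hop_length, "audio")
}
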