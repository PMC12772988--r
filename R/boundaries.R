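#' Framewise boundary-probability series
#'
#' The per-frame probability that a breathing boundary (the start of the
#' louder breath phase) occurs at that frame — the detector's softmax
#' class-1 output.
#'
#' @param p1 Numeric vector of probabilities in `[0, 1]`.
#' @param frame_rate Frames per second.
#' @return An object of class `boundary_probs`.
#' @export
boundary_probs <- function(p1, frame_rate) {
  p1 <- as.numeric(p1)
  if (any(!is.finite(p1)) || any(p1 < 0) || any(p1 > 1))
    stop("p1 must be probabilities in [0, 1]")
  structure(list(p1 = p1, frame_rate = as.numeric(frame_rate)),
            class = "boundary_probs")
}

#' @export
print.boundary_probs <- function(x, ...) {
  cat(sprintf("<boundary_probs> %d frames @ %.3f frames/s\n",
              length(x$p1), x$frame_rate))
  invisible(x)
}

#' Choose the louder breath phase
#'
#' Breathing boundaries are defined at the start of whichever phase
#' (inspiration or expiration) is louder for the subject. Loudness is the
#' mean over same-phase segments of the per-segment average sample power;
#' equal powers break to inspiration. If only one phase is annotated it wins.
#'
#' @param clip An [audio_clip()].
#' @param ann An [annotation_track()].
#' @return `"inspiration"` or `"expiration"`.
#' @export
choose_louder_phase <- function(clip, ann) {
  stopifnot(inherits(clip, "audio_clip"), inherits(ann, "annotation_track"))
  if (nrow(ann) == 0L) stop("empty annotation track")
  phases <- unique(ann$phase)
  if (length(phases) == 1L) return(phases)
  sr <- clip$sample_rate
  n <- length(clip$samples)
  mean_power <- function(ph) {
    s <- ann[ann$phase == ph, , drop = FALSE]
    mean(vapply(seq_len(nrow(s)), function(i) {
      i0 <- max(1L, round(s$start[i] * sr) + 1L)
      i1 <- min(n, round(s$end[i] * sr))
      mean(clip$samples[i0:i1]^2)
    }, numeric(1)))
  }
  if (mean_power("expiration") > mean_power("inspiration"))
    "expiration" else "inspiration"
}

#' Boundary frames from annotations
#'
#' Maps the start times of the chosen phase's segments to 1-based frame
#' indices on a feature time axis.
#'
#' @param ann An [annotation_track()].
#' @param phase Which phase's starts are boundaries.
#' @param frame_rate Frames per second of the feature matrix.
#' @param n_frames Number of frames (boundaries beyond the end are dropped).
#' @return Integer vector of boundary frames.
#' @export
boundary_frames <- function(ann, phase, frame_rate, n_frames) {
  stopifnot(inherits(ann, "annotation_track"))
  s <- ann[ann$phase == phase, , drop = FALSE]
  f <- round(s$start * frame_rate) + 1L
  as.integer(f[f >= 1L & f <= n_frames])
}

#' Widened framewise boundary labels
#'
#' Boundary frames are vastly outnumbered by non-boundary frames, so each
#' boundary `b` is widened to `widen_width` frames of class 1 (default 10:
#' frames `b-5 .. b+4`; the even width is pinned to this left-heavy
#' centering), clipped to the clip edges; overlapping windows take the
#' union.
#'
#' @param boundaries 1-based boundary frame indices.
#' @param n_frames Total number of frames.
#' @param widen_width Width of each class-1 window in frames.
#' @return A `boundary_labels` object: list with `labels` (0/1 integer
#'   vector of length `n_frames`), `boundary_frames`, `widen_width`.
#' @export
make_boundary_labels <- function(boundaries, n_frames, widen_width = 10L) {
  boundaries <- as.integer(boundaries)
  if (any(boundaries < 1L | boundaries > n_frames))
    stop("boundary frame out of range")
  half <- widen_width %/% 2L
  labels <- integer(n_frames)
  for (b in boundaries) {
    lo <- max(1L, b - half)
    hi <- min(n_frames, b + widen_width - half - 1L)
    labels[lo:hi] <- 1L
  }
  structure(list(labels = labels, boundary_frames = boundaries,
                 widen_width = as.integer(widen_width)),
            class = "boundary_labels")
}

#' Frequency-permutation augmentation
#'
#' Shuffles spectrogram channels with a seeded uniform random permutation,
#' leaving the time axis untouched. Temporal periodicity is preserved under
#' channel shuffling, so this augments training data without changing the
#' supervision; it is applied per clip, per epoch, during training only.
#'
#' @param X An audio-modality [frame_features()].
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @param perm Optional explicit permutation (overrides `seed`).
#' @return A [frame_features()] with permuted rows; the permutation is
#'   attached as attribute `"perm"`.
#' @export
frequency_permute <- function(X, seed = 1L, perm = NULL) {
  stopifnot(inherits(X, "frame_features"))
  if (X$modality != "audio") stop("frequency permutation is audio-only")
  if (is.null(perm)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    perm <- sample.int(nrow(X$values))
  }
  out <- frame_features(X$values[perm, , drop = FALSE], X$frame_rate, "audio")
  attr(out, "perm") <- perm
  out
}

#' Boundary detector configuration
#'
#' Architecture and training hyperparameters for the boundary detector: two
#' bidirectional LSTM layers, two fully-connected layers, softmax over two
#' classes. Defaults are a reduced hidden size suitable for desk-scale
#' synthetic training; all values are configurable.
#'
#' @param hidden_size Hidden units per BLSTM direction.
#' @param fc_size Units in the first fully-connected layer.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param clip_norm Global gradient-norm clip (0 disables).
#' @param class_weights `"inverse"` for inverse-frequency class weights, or
#'   a numeric `c(w0, w1)`.
#' @param augment Apply frequency permutation each epoch (train-time only).
#' @param seed Seed for weight initialization, clip order, and permutations.
#' @return A `boundary_model_config` list.
#' @export
boundary_model_config <- function(hidden_size = 16L, fc_size = 32L,
                                  lr = 2e-3, epochs = 8L, clip_norm = 5,
                                  class_weights = "inverse", augment = TRUE,
                                  seed = 1L) {
  structure(list(hidden_size = as.integer(hidden_size),
                 fc_size = as.integer(fc_size), lr = lr,
                 epochs = as.integer(epochs), clip_norm = clip_norm,
                 class_weights = class_weights, augment = augment,
                 seed = as.integer(seed)),
            class = "boundary_model_config")
}

# per-clip channel z-scoring applied before the network
.normalize_clip <- function(values) {
  m <- rowMeans(values)
  s <- sqrt(rowMeans((values - m)^2))
  s[s == 0] <- 1
  (values - m) / s
}

#' Train the breathing-boundary detector
#'
#' Trains the BLSTM framewise classifier on (feature matrix, label series)
#' pairs: per-clip channel z-scoring, weighted cross-entropy, Adam, one clip
#' per optimizer step, optional frequency-permutation augmentation redrawn
#' each epoch. Training is deterministic given `cfg$seed` (weights, clip
#' order and permutations are all drawn from it).
#'
#' @param features List of audio [frame_features()] (80 x T each).
#' @param labels List of [make_boundary_labels()] results (or plain 0/1
#'   vectors), matching `features` in length and frame count.
#' @param cfg A [boundary_model_config()].
#' @return A `boundary_model`: list with `weights`, `loss` (per-epoch
#'   training loss), `cfg`, `n_channels`, `frame_rate`.
#' @export
train_boundary_model <- function(features, labels,
                                 cfg = boundary_model_config()) {
  if (length(features) == 0L) stop("empty dataset")
  if (length(features) != length(labels)) stop("features/labels mismatch")
  stopifnot(all(vapply(features, inherits, logical(1), "frame_features")))
  if (any(vapply(features, function(f) f$modality, "") != "audio"))
    stop("boundary detector expects audio-modality features")
  D <- nrow(features[[1L]]$values)
  X_list <- lapply(features, function(f) .normalize_clip(f$values))
  y_list <- lapply(labels, function(l) {
    y <- if (inherits(l, "boundary_labels")) l$labels else as.integer(l)
    y
  })
  for (i in seq_along(X_list)) {
    if (length(y_list[[i]]) != ncol(X_list[[i]]))
      stop("label length != frame count for clip ", i)
  }
  w <- cfg$class_weights
  if (identical(w, "inverse")) {
    n1 <- sum(vapply(y_list, sum, numeric(1)))
    n_all <- sum(vapply(y_list, length, numeric(1)))
    n0 <- n_all - n1
    if (n1 == 0) stop("no class-1 frames in the dataset")
    w <- c(n_all / (2 * n0), n_all / (2 * n1))
  }

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  H1 <- cfg$hidden_size; H2 <- cfg$hidden_size
  init <- list(
    l1f_W = .winit(4L * H1, D), l1f_U = .winit(4L * H1, H1),
    l1f_b = .lstm_bias(H1),
    l1b_W = .winit(4L * H1, D), l1b_U = .winit(4L * H1, H1),
    l1b_b = .lstm_bias(H1),
    l2f_W = .winit(4L * H2, 2L * H1), l2f_U = .winit(4L * H2, H2),
    l2f_b = .lstm_bias(H2),
    l2b_W = .winit(4L * H2, 2L * H1), l2b_U = .winit(4L * H2, H2),
    l2b_b = .lstm_bias(H2),
    fc1_W = .winit(cfg$fc_size, 2L * H2), fc1_b = numeric(cfg$fc_size),
    fc2_W = .winit(2L, cfg$fc_size), fc2_b = numeric(2L))
  n <- length(X_list)
  order_mat <- t(vapply(seq_len(cfg$epochs), function(e) sample.int(n),
                        integer(n)))
  if (cfg$epochs == 1L) order_mat <- matrix(order_mat, nrow = 1L)
  perm_list <- lapply(seq_len(cfg$epochs), function(e) {
    if (cfg$augment) lapply(seq_len(n), function(i) sample.int(D))
    else list()
  })
  fit <- .blstm_train_cpp(X_list, y_list, init, cfg$lr, cfg$epochs,
                          w[1L], w[2L], order_mat, perm_list, cfg$clip_norm)
  structure(list(weights = fit$weights, loss = as.numeric(fit$loss),
                 cfg = cfg, n_channels = D,
                 frame_rate = features[[1L]]$frame_rate),
            class = "boundary_model")
}

.winit <- function(r, c) {
  s <- sqrt(6 / (r + c))
  matrix(stats::runif(r * c, -s, s), r, c)
}

# forget-gate bias 1 (standard LSTM practice); others 0
.lstm_bias <- function(H) c(numeric(H), rep(1, H), numeric(2L * H))

#' @export
print.boundary_model <- function(x, ...) {
  cat(sprintf(paste0("<boundary_model> %d input channels, hidden %d/dir, ",
                     "%d epochs (final loss %.4f)\n"),
              x$n_channels, x$cfg$hidden_size, length(x$loss),
              x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict boundary probabilities
#'
#' Runs the trained detector on an audio feature matrix (z-scored per
#' channel, as in training; no permutation at prediction time) and returns
#' the framewise class-1 softmax probability.
#'
#' @param model A `boundary_model` from [train_boundary_model()].
#' @param X An audio [frame_features()] with the model's channel count.
#' @return A [boundary_probs()] of length `ncol(X$values)`.
#' @export
predict_boundaries <- function(model, X) {
  stopifnot(inherits(model, "boundary_model"), inherits(X, "frame_features"))
  if (nrow(X$values) != model$n_channels)
    stop("channel mismatch: model expects ", model$n_channels, ", got ",
         nrow(X$values))
  p1 <- .blstm_predict_cpp(model$weights, .normalize_clip(X$values))
  boundary_probs(pmin(1, pmax(0, p1)), X$frame_rate)
}

#' Save / load a boundary model
#'
#' Checkpoints are JSON (format version 1): configuration, channel count,
#' frame rate and all weight matrices at full double precision.
#'
#' @param model A `boundary_model`.
#' @param path Checkpoint path.
#' @return `path` invisibly (`save_boundary_model`); a `boundary_model`
#'   (`load_boundary_model`).
#' @export
save_boundary_model <- function(model, path) {
  stopifnot(inherits(model, "boundary_model"))
  obj <- list(format = "respirate-boundary-model", version = 1L,
              cfg = unclass(model$cfg), n_channels = model$n_channels,
              frame_rate = model$frame_rate, loss = model$loss,
              weights = lapply(model$weights, function(w) {
                if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
                else list(dim = NULL, data = as.numeric(w))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_boundary_model
#' @export
load_boundary_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "respirate-boundary-model"))
    stop("not a boundary-model checkpoint: ", path)
  weights <- lapply(obj$weights, function(w) {
    if (!is.null(w$dim)) matrix(w$data, w$dim[1L], w$dim[2L]) else w$data
  })
  cfg <- obj$cfg
  class(cfg) <- "boundary_model_config"
  structure(list(weights = weights, loss = obj$loss, cfg = cfg,
                 n_channels = obj$n_channels, frame_rate = obj$frame_rate),
            class = "boundary_model")
}

#' Respiratory rate from boundary probabilities
#'
#' Treats the framewise boundary probabilities as a one-channel feature
#' matrix and applies the autocorrelation estimator with `k = 1` — the
#' "autocorrelation on the probabilities" route.
#'
#' @param p A [boundary_probs()].
#' @param prior_shape,prior_mode_s,prior_sigma_log,min_lag_s,max_lag_s As in
#'   [estimate_rr_autocorr()].
#' @return An [rr_estimate()] with method `"bb"`.
#' @export
rr_from_boundaries <- function(p, prior_shape = c("lognormal", "flat"),
                               prior_mode_s = 3, prior_sigma_log = 0.5,
                               min_lag_s = 1, max_lag_s = 10) {
  stopifnot(inherits(p, "boundary_probs"))
  prior_shape <- match.arg(prior_shape)
  X <- frame_features(matrix(p$p1, nrow = 1L), p$frame_rate, "audio")
  est <- estimate_rr_autocorr(X, k = 1L, prior_shape = prior_shape,
                              prior_mode_s = prior_mode_s,
                              prior_sigma_log = prior_sigma_log,
                              min_lag_s = min_lag_s, max_lag_s = max_lag_s,
                              standardize = FALSE)
  est$method <- "bb"
  est
}
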