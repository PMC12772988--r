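#' Synthetic breathing audio
#'
#' Generates an 8 kHz clip of alternating inspiration/expiration noise bursts
#' over low-level room tone, with boundary annotations. Inspiration onsets
#' are spaced by `60/true_rate + N(0, interval_jitter_sd^2)` seconds; each
#' cycle's expiration starts a fixed fraction into the interval. Bursts are
#' band-passed white noise under a raised-cosine (Tukey-style) onset/offset
#' envelope. Inspiration and expiration occupy distinct frequency bands
#' (defaults 200-900 Hz and 1100-2600 Hz): real breath phases differ
#' spectrally, and the separation keeps each spectral channel periodic at the
#' full breath cycle rather than at the inspiration-to-expiration spacing.
#' Generation is deterministic per seed.
#'
#' @param duration_s Clip length in seconds (must cover >= 3 breath
#'   intervals).
#' @param true_rate Mean respiratory rate in breaths/min.
#' @param interval_jitter_sd SD of the inter-breath interval in seconds.
#' @param insp_dur_s,exp_dur_s Burst durations in seconds.
#' @param insp_band,exp_band Band-pass ranges in Hz, `c(lo, hi)`.
#' @param expiration_gain_db Expiration level relative to inspiration, dB.
#' @param breath_gain_jitter_db Per-breath level variability (SD of a
#'   Gaussian gain in dB applied to each cycle; real breathing varies
#'   breath to breath).
#' @param burst_level RMS amplitude of the inspiration bursts.
#' @param room_tone_level RMS amplitude of the room tone (white noise floor).
#' @param exp_offset_frac Fraction of the interval at which expiration
#'   starts.
#' @param sample_rate Output sample rate in Hz.
#' @param seed Integer seed.
#' @return List with `clip` (an [audio_clip()]), `annotations` (an
#'   [annotation_track()]) and `spec` (the resolved parameters).
#' @export
synth_breath_audio <- function(duration_s = 60, true_rate = 20,
                               interval_jitter_sd = 0.2,
                               insp_dur_s = 0.6, exp_dur_s = 0.7,
                               insp_band = c(200, 900),
                               exp_band = c(1100, 2600),
                               expiration_gain_db = 6,
                               breath_gain_jitter_db = 2,
                               burst_level = 0.1, room_tone_level = 0.003,
                               exp_offset_frac = 0.45, sample_rate = 8000,
                               seed = 1L) {
  interval <- 60 / true_rate
  if (duration_s < 3 * interval)
    stop("duration must cover at least 3 breath intervals")
  if (insp_dur_s >= interval * exp_offset_frac ||
      exp_dur_s >= interval * (1 - exp_offset_frac))
    stop("burst longer than its share of the breath interval")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  n <- round(duration_s * sample_rate)
  x <- stats::rnorm(n, sd = room_tone_level)

  starts <- c()
  t0 <- interval * 0.5
  # breaths cannot overlap: drawn intervals are floored just above the burst
  # durations (a ~2.5+ sigma event at the default settings)
  min_interval <- max(insp_dur_s, exp_dur_s) + 0.1
  while (t0 < duration_s) {
    starts <- c(starts, t0)
    t0 <- t0 + max(min_interval,
                   interval + stats::rnorm(1L, sd = interval_jitter_sd))
  }
  exp_gain <- 10^(expiration_gain_db / 20)
  ph <- c(); s0 <- c(); s1 <- c()
  for (b in starts) {
    gap <- interval * exp_offset_frac
    e <- b + gap
    cycle_gain <- 10^(stats::rnorm(1L, sd = breath_gain_jitter_db) / 20)
    for (seg in list(list("inspiration", b, insp_dur_s, insp_band, cycle_gain),
                     list("expiration", e, exp_dur_s, exp_band,
                          cycle_gain * exp_gain))) {
      st <- seg[[2]]; du <- seg[[3]]
      if (st + du > duration_s) next
      burst <- .noise_burst(round(du * sample_rate), seg[[4]], sample_rate)
      burst <- burst / sqrt(mean(burst^2)) * burst_level * seg[[5]]
      i0 <- round(st * sample_rate) + 1L
      idx <- i0:(i0 + length(burst) - 1L)
      x[idx] <- x[idx] + burst
      ph <- c(ph, seg[[1]]); s0 <- c(s0, st); s1 <- c(s1, st + du)
    }
  }
  list(clip = audio_clip(x, sample_rate),
       annotations = annotation_track(ph, s0, s1),
       spec = list(duration_s = duration_s, true_rate = true_rate,
                   interval_jitter_sd = interval_jitter_sd,
                   expiration_gain_db = expiration_gain_db,
                   burst_level = burst_level,
                   room_tone_level = room_tone_level, seed = seed))
}

# band-passed white noise under a raised-cosine onset/offset envelope
.noise_burst <- function(n, band, sample_rate, ramp_frac = 0.25) {
  w <- band / (sample_rate / 2)
  bf <- signal::butter(4, w, type = "pass")
  y <- signal::filtfilt(bf, stats::rnorm(n))
  r <- max(2L, round(n * ramp_frac))
  env <- rep(1, n)
  ramp <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = r))
  env[1:r] <- ramp
  env[(n - r + 1L):n] <- rev(ramp)
  y * env
}

.save_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic periodic video grid features
#'
#' Emulates the 84-channel grid features of chest-motion video: a seeded
#' random subset of channels carries `amplitude * sin(2*pi*rate/60*t + phi)`
#' plus linear drift and Gaussian noise; the remaining channels carry drift
#' and noise only. Per-channel drift slopes and phases are randomized within
#' the stated scales.
#'
#' @param duration_s Length in seconds.
#' @param true_rate Breaths per minute carried by the periodic channels.
#' @param n_channels Total channels (default 84).
#' @param n_periodic Number of periodic channels.
#' @param amplitude Sinusoid amplitude (intensity units).
#' @param drift_slope Scale of per-channel linear drift (units/s).
#' @param noise_sd Additive Gaussian noise SD.
#' @param frame_rate Frames per second (default 29.9, the video rate).
#' @param seed Integer seed.
#' @return List with `features` (a [frame_features()], modality video),
#'   `periodic_channels` (indices of the planted channels) and `true_rate`.
#' @export
synth_video_features <- function(duration_s = 60, true_rate = 20,
                                 n_channels = 84L, n_periodic = 8L,
                                 amplitude = 1, drift_slope = 0.02,
                                 noise_sd = 0.3, frame_rate = 29.9,
                                 seed = 1L) {
  if (n_periodic < 1L || n_periodic > n_channels)
    stop("n_periodic must be in [1, n_channels]")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  T_frames <- round(duration_s * frame_rate)
  t <- (seq_len(T_frames) - 1L) / frame_rate
  periodic <- sort(sample.int(n_channels, n_periodic))
  X <- matrix(stats::rnorm(n_channels * T_frames, sd = noise_sd),
              n_channels, T_frames)
  slopes <- stats::runif(n_channels, -drift_slope, drift_slope)
  X <- X + outer(slopes, t)
  phases <- stats::runif(n_periodic, 0, 2 * pi)
  for (j in seq_along(periodic)) {
    X[periodic[j], ] <- X[periodic[j], ] +
      amplitude * sin(2 * pi * true_rate / 60 * t + phases[j])
  }
  list(features = frame_features(X, frame_rate, "video"),
       periodic_channels = periodic, true_rate = true_rate)
}

#' Synthetic breathing-boundary probability series
#'
#' Emulates the framewise output of a boundary detector: a noisy baseline
#' with smooth bumps of probability at jittered breath boundaries. A fraction
#' of boundaries may be dropped (missed detections). Values are clipped to
#' `[0, 1]`. The true boundary frames are returned for scoring.
#'
#' @param duration_s Length in seconds.
#' @param true_rate Breaths per minute.
#' @param interval_jitter_sd SD of the inter-boundary interval in seconds.
#' @param peak Bump height at a boundary.
#' @param peak_width_frames Gaussian bump SD in frames.
#' @param baseline Mean off-boundary probability.
#' @param noise_sd Additive framewise noise SD.
#' @param miss_prob Probability a boundary produces no bump.
#' @param frame_rate Frames per second.
#' @param seed Integer seed.
#' @return List with `p` (a `boundary_probs` object, see
#'   [boundary_probs()]), `boundary_frames` (1-based true boundary frames)
#'   and `true_rate`.
#' @export
synth_boundary_probs <- function(duration_s = 30, true_rate = 20,
                                 interval_jitter_sd = 0.2, peak = 0.85,
                                 peak_width_frames = 2, baseline = 0.05,
                                 noise_sd = 0.1, miss_prob = 0,
                                 frame_rate = 29.96, seed = 1L) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  T_frames <- round(duration_s * frame_rate)
  interval <- 60 / true_rate
  times <- c()
  t0 <- interval * 0.5
  while (t0 < duration_s) {
    times <- c(times, t0)
    t0 <- t0 + interval + stats::rnorm(1L, sd = interval_jitter_sd)
  }
  frames <- pmin(T_frames, pmax(1L, round(times * frame_rate) + 1L))
  p <- rep(baseline, T_frames) + stats::rnorm(T_frames, sd = noise_sd)
  grid <- seq_len(T_frames)
  for (f in frames) {
    if (miss_prob > 0 && stats::runif(1L) < miss_prob) next
    p <- p + peak * exp(-(grid - f)^2 / (2 * peak_width_frames^2))
  }
  list(p = boundary_probs(pmin(1, pmax(0, p)), frame_rate),
       boundary_frames = frames, true_rate = true_rate)
}

#' Seeded noise generators
#'
#' `noise_clip()` produces white, pink (1/f, via the Kasdin IIR
#' approximation) or babble-like (sum of many random tones with slow random
#' amplitude modulation) noise at unit RMS.
#'
#' @param duration_s Length in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param kind `"pink"`, `"white"` or `"babble"`.
#' @param seed Integer seed.
#' @return An [audio_clip()] with RMS 1.
#' @export
noise_clip <- function(duration_s, sample_rate = 8000,
                       kind = c("pink", "white", "babble"), seed = 1L) {
  kind <- match.arg(kind)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  n <- round(duration_s * sample_rate)
  x <- switch(kind,
    white = stats::rnorm(n),
    pink = {
      b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
      a <- c(1, -2.494956002, 2.017265875, -0.522189400)
      as.numeric(signal::filter(signal::Arma(b = b, a = a), stats::rnorm(n)))
    },
    babble = {
      freqs <- stats::runif(40L, 100, 3500)
      tgrid <- seq_len(n) / sample_rate
      y <- 0
      for (f in freqs) {
        am <- 1 + 0.5 * sin(2 * pi * stats::runif(1L, 0.5, 4) * tgrid +
                            stats::runif(1L, 0, 2 * pi))
        y <- y + am * sin(2 * pi * f * tgrid + stats::runif(1L, 0, 2 * pi))
      }
      y
    })
  audio_clip(x / sqrt(mean(x^2)), sample_rate)
}

#' Mix noise into a signal at a target SNR
#'
#' Rescales `noise` so that `10*log10(P_signal / P_noise) == target_db` over
#' the full clip (powers are mean squared amplitude) and returns the sum.
#' Noise shorter than the signal is tiled from a seeded random offset;
#' longer noise is truncated. `target_db = Inf` returns the signal
#' unchanged.
#'
#' @param signal_clip,noise Two [audio_clip()]s at equal sample rates.
#' @param target_db Target SNR in dB, or `Inf` for clean.
#' @param seed Seed for the tiling offset.
#' @return An [audio_clip()]; attribute `"noise_scale"` holds the factor
#'   applied to the noise.
#' @export
mix_at_snr <- function(signal_clip, noise, target_db, seed = 1L) {
  stopifnot(inherits(signal_clip, "audio_clip"), inherits(noise, "audio_clip"))
  if (is.infinite(target_db) && target_db > 0) return(signal_clip)
  if (abs(signal_clip$sample_rate - noise$sample_rate) > 1e-9)
    stop("sample rates differ")
  n <- length(signal_clip$samples)
  v <- noise$samples
  if (length(v) < n) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    off <- sample.int(length(v), 1L)
    v <- rep(c(v[off:length(v)], v[seq_len(off - 1L)]),
             length.out = n)
  } else v <- v[seq_len(n)]
  p_sig <- mean(signal_clip$samples^2)
  p_noi <- mean(v^2)
  if (p_sig == 0 || p_noi == 0) stop("zero-power signal or noise")
  scale <- sqrt(p_sig / (p_noi * 10^(target_db / 10)))
  out <- audio_clip(signal_clip$samples + scale * v,
                    signal_clip$sample_rate)
  attr(out, "noise_scale") <- scale
  out
}

#' Measure annotation-based SNR
#'
#' The recording-quality measure used for breath audio: the average power of
#' the two loudest annotated breath segments (inspiration or expiration)
#' divided by the power of the room tone in the gaps between annotated
#' segments, in dB. With a single annotated segment that segment alone is
#' used (with a warning).
#'
#' @param clip An [audio_clip()].
#' @param ann An [annotation_track()] on the same time axis.
#' @return SNR in dB.
#' @export
measure_snr <- function(clip, ann) {
  stopifnot(inherits(clip, "audio_clip"), inherits(ann, "annotation_track"))
  if (nrow(ann) < 1L) stop("no annotated segments")
  sr <- clip$sample_rate
  n <- length(clip$samples)
  seg_power <- vapply(seq_len(nrow(ann)), function(i) {
    i0 <- max(1L, round(ann$start[i] * sr) + 1L)
    i1 <- min(n, round(ann$end[i] * sr))
    mean(clip$samples[i0:i1]^2)
  }, numeric(1))
  loud <- sort(seg_power, decreasing = TRUE)
  if (length(loud) < 2L) {
    warning("only one annotated segment; using it alone")
    top <- loud[1L]
  } else top <- mean(loud[1:2])

  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(ann))) {
    i0 <- max(1L, round(ann$start[i] * sr) + 1L)
    i1 <- min(n, round(ann$end[i] * sr))
    covered[i0:i1] <- TRUE
  }
  first <- max(1L, round(min(ann$start) * sr) + 1L)
  last <- min(n, round(max(ann$end) * sr))
  gap <- !covered & seq_len(n) >= first & seq_len(n) <= last
  if (!any(gap)) {
    # degenerate tracks (e.g. a single segment) have no between-breath
    # span; fall back to everything outside the annotated segments
    gap <- !covered
    if (!any(gap)) stop("no inter-segment gaps")
  }
  10 * log10(top / mean(clip$samples[gap]^2))
}
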