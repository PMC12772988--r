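#' Mean absolute error
#'
#' @param truth,est Equal-length numeric vectors of reference and estimated
#'   rates (breaths/min).
#' @return Mean of `abs(est - truth)`.
#' @export
mae <- function(truth, est) {
  if (length(truth) != length(est)) stop("length mismatch")
  if (length(truth) == 0L) stop("empty input")
  mean(abs(est - truth))
}

#' Bland-Altman statistics
#'
#' Agreement between paired measurements: the mean difference `d = est -
#' truth` and the limits of agreement `mean(d) +/- 1.96 sd(d)` (sample SD,
#' n-1 denominator).
#'
#' @param truth,est Equal-length numeric vectors, length >= 2.
#' @return Named list `mean_diff`, `lo`, `hi`, `sd_diff`.
#' @export
bland_altman <- function(truth, est) {
  if (length(truth) != length(est)) stop("length mismatch")
  if (length(truth) < 2L) stop("need at least 2 pairs")
  d <- est - truth
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, lo = m - 1.96 * s, hi = m + 1.96 * s, sd_diff = s)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of scores for a binary label; used to
#' judge framewise boundary ranking.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("need both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Welch two-sample comparison of absolute errors
#'
#' Reporting utility mirroring the method-comparison tests: a two-tailed
#' Welch t-test on the per-sample absolute errors of two methods (absolute
#' errors, not raw estimates, so the comparison is of accuracy).
#'
#' @param truth Reference rates.
#' @param est_a,est_b Estimates from the two methods.
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_methods <- function(truth, est_a, est_b) {
  stats::t.test(abs(est_a - truth), abs(est_b - truth),
                var.equal = FALSE, alternative = "two.sided")
}

#' Noise-robustness sweep
#'
#' For each SNR level (and a `"clean"` row), generates `n_per_level` seeded
#' synthetic breathing clips, mixes in noise at that level, runs the
#' estimator, and reports the MAE against the generator's true rates. The
#' same per-replicate seeds (and hence the same clips) are used at every
#' level, so rows are comparable.
#'
#' @param estimator Function `(audio_clip) -> rr_estimate`.
#' @param snr_levels_db Numeric SNR levels in dB; `Inf` entries and the
#'   always-included first row mean clean (no noise).
#' @param n_per_level Replicates per level.
#' @param rates Vector of true rates cycled over replicates.
#' @param duration_s Clip length in seconds.
#' @param noise_kind Passed to [noise_clip()].
#' @param seed Base seed; replicate i uses `seed * 1000 + i`.
#' @param ... Passed to [synth_breath_audio()].
#' @return A data.frame with columns `snr_db` (`Inf` = clean), `mae`, `n`.
#' @export
noise_sweep <- function(estimator, snr_levels_db = c(10, 5, 0, -5, -10),
                        n_per_level = 10L, rates = c(12, 15, 20, 24, 30),
                        duration_s = 60, noise_kind = "pink", seed = 1L,
                        ...) {
  if (!length(snr_levels_db)) stop("snr_levels_db must be nonempty")
  levels <- unique(c(Inf, snr_levels_db))
  reps <- seq_len(n_per_level)
  truth <- rates[(reps - 1L) %% length(rates) + 1L]
  clips <- lapply(reps, function(i) {
    synth_breath_audio(duration_s = duration_s, true_rate = truth[i],
                       seed = seed * 1000L + i, ...)$clip
  })
  rows <- lapply(levels, function(lv) {
    est <- vapply(reps, function(i) {
      clip <- clips[[i]]
      if (is.finite(lv)) {
        nz <- noise_clip(duration_s, clip$sample_rate, noise_kind,
                         seed = seed * 1000L + 500L + i)
        clip <- mix_at_snr(clip, nz, lv)
      }
      estimator(clip)$rate
    }, numeric(1))
    data.frame(snr_db = lv, mae = mae(truth, est), n = n_per_level)
  })
  do.call(rbind, rows)
}

#' Bland-Altman plot
#'
#' Side-effect-free ggplot of paired differences against means with the
#' mean-difference and limits-of-agreement lines. Requires ggplot2.
#'
#' @param truth,est As in [bland_altman()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(truth, est) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ba <- bland_altman(truth, est)
  d <- data.frame(mean = (truth + est) / 2, diff = est - truth)
  ggplot2::ggplot(d, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$lo, ba$hi), linetype = 2) +
    ggplot2::labs(x = "Mean of truth and estimate (breaths/min)",
                  y = "Estimate - truth (breaths/min)")
}
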