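test_that("breath audio is deterministic with exact spacing at zero jitter", {
  g1 <- synth_breath_audio(duration_s = 30, true_rate = 20,
                           interval_jitter_sd = 0, breath_gain_jitter_db = 0,
                           seed = 6)
  g2 <- synth_breath_audio(duration_s = 30, true_rate = 20,
                           interval_jitter_sd = 0, breath_gain_jitter_db = 0,
                           seed = 6)
  expect_identical(g1$clip$samples, g2$clip$samples)
  expect_identical(g1$annotations, g2$annotations)

  insp <- g1$annotations$start[g1$annotations$phase == "inspiration"]
  expect_equal(diff(insp), rep(3, length(insp) - 1), tolerance = 1e-9)

  expect_error(synth_breath_audio(duration_s = 5, true_rate = 20),
               "3 breath intervals")
  expect_error(synth_breath_audio(duration_s = 60, true_rate = 40,
                                  insp_dur_s = 1.2),
               "longer than its share")
})

test_that("expiration gain raises measured expiration power", {
  g <- synth_breath_audio(duration_s = 30, true_rate = 15,
                          expiration_gain_db = 6, breath_gain_jitter_db = 0,
                          interval_jitter_sd = 0, seed = 2)
  ann <- g$annotations
  sr <- g$clip$sample_rate
  pw <- function(ph) {
    s <- ann[ann$phase == ph, ]
    mean(vapply(seq_len(nrow(s)), function(i) {
      idx <- (round(s$start[i] * sr) + 1):round(s$end[i] * sr)
      mean(g$clip$samples[idx]^2)
    }, numeric(1)))
  }
  expect_equal(10 * log10(pw("expiration") / pw("inspiration")), 6,
               tolerance = 0.5)
})

test_that("annotated intervals track the requested rate under jitter", {
  for (seed in 1:5) {
    g <- synth_breath_audio(duration_s = 90, true_rate = 20,
                            interval_jitter_sd = 0.2, seed = seed)
    insp <- g$annotations$start[g$annotations$phase == "inspiration"]
    iv <- diff(insp)
    expect_lt(abs(mean(iv) - 3), 3 * 0.2 / sqrt(length(iv)) + 1e-9)
  }
})

test_that("video features plant periodicity in the declared channels", {
  g <- synth_video_features(duration_s = 20, true_rate = 24, n_periodic = 84,
                            noise_sd = 0, drift_slope = 0, seed = 4)
  t <- (seq_len(ncol(g$features$values)) - 1) / g$features$frame_rate
  for (ch in c(1, 40, 84)) {
    x <- g$features$values[ch, ]
    # exactly sinusoidal at the stated rate: project onto the two quadratures
    c1 <- 2 * mean(x * sin(2 * pi * 24 / 60 * t))
    c2 <- 2 * mean(x * cos(2 * pi * 24 / 60 * t))
    expect_equal(sqrt(c1^2 + c2^2), 1, tolerance = 0.02)
    expect_lt(max(abs(x - c1 * sin(2 * pi * 24 / 60 * t) -
                        c2 * cos(2 * pi * 24 / 60 * t))), 1e-6)
  }

  g1 <- synth_video_features(seed = 11)
  g2 <- synth_video_features(seed = 11)
  expect_identical(g1$features$values, g2$features$values)

  # variance ranking recovers the planted subset
  g <- synth_video_features(duration_s = 60, true_rate = 20, n_periodic = 8,
                            seed = 9)
  est <- estimate_rr_autocorr(g$features, k = 8)
  expect_setequal(est$diagnostics$selected, g$periodic_channels)

  expect_error(synth_video_features(n_periodic = 0), "n_periodic")
})

test_that("SNR mixing hits the target power ratio exactly", {
  sig <- synth_breath_audio(duration_s = 20, true_rate = 20, seed = 1)$clip
  for (target in c(10, 0, -10)) {
    nz <- noise_clip(20, 8000, "white", seed = 2)
    mixed <- mix_at_snr(sig, nz, target)
    scale <- attr(mixed, "noise_scale")
    added <- mixed$samples - sig$samples
    got <- 10 * log10(mean(sig$samples^2) / mean(added^2))
    expect_equal(got, target, tolerance = 0.01)
    expect_equal(mean(added^2), scale^2 * mean(nz$samples[1:160000]^2),
                 tolerance = 1e-9)
  }

  expect_identical(mix_at_snr(sig, noise_clip(20, 8000, seed = 1), Inf), sig)
  silence <- audio_clip(numeric(1000), 8000)
  expect_error(mix_at_snr(silence, noise_clip(1, 8000), 0), "zero-power")
})

test_that("short noise is tiled to cover the signal", {
  sig <- audio_clip(rep(c(0.3, -0.3), 8000), 8000)
  nz <- noise_clip(0.25, 8000, "white", seed = 5)
  mixed <- mix_at_snr(sig, nz, 0)
  expect_length(mixed$samples, length(sig$samples))
  expect_equal(mean((mixed$samples - sig$samples)^2), mean(sig$samples^2),
               tolerance = 1e-6)
})

test_that("noise generators are seeded and unit power", {
  for (kind in c("white", "pink", "babble")) {
    a <- noise_clip(2, 8000, kind, seed = 3)
    b <- noise_clip(2, 8000, kind, seed = 3)
    expect_identical(a$samples, b$samples)
    expect_equal(mean(a$samples^2), 1, tolerance = 1e-9)
  }
  # pink noise concentrates power at low frequencies
  pink <- noise_clip(4, 8000, "pink", seed = 7)
  spec <- Mod(stats::fft(pink$samples))^2
  lo <- sum(spec[2:2000]); hi <- sum(spec[14001:16000])
  expect_gt(lo, 5 * hi)
})

test_that("annotation-based SNR matches its construction", {
  sr <- 8000
  x <- rep(0.01, 6 * sr)
  seg <- annotation_track(c("inspiration", "expiration", "inspiration"),
                          c(0.5, 2.5, 4.5), c(1.0, 3.0, 5.0))
  for (i in seq_len(nrow(seg))) {
    idx <- (round(seg$start[i] * sr) + 1):round(seg$end[i] * sr)
    x[idx] <- 0.01
  }
  clip <- audio_clip(x, sr)
  expect_equal(measure_snr(clip, seg), 0, tolerance = 1e-9)

  # 20 dB bursts over room tone
  x2 <- rep(0.01, 6 * sr)
  for (i in seq_len(nrow(seg))) {
    idx <- (round(seg$start[i] * sr) + 1):round(seg$end[i] * sr)
    x2[idx] <- 0.1
  }
  expect_equal(measure_snr(audio_clip(x2, sr), seg), 20, tolerance = 1e-6)

  # generator round-trip within envelope tolerance
  g <- synth_breath_audio(duration_s = 40, true_rate = 15,
                          burst_level = 0.1, room_tone_level = 0.01,
                          expiration_gain_db = 0, breath_gain_jitter_db = 0,
                          interval_jitter_sd = 0, seed = 12)
  expect_equal(measure_snr(g$clip, g$annotations), 20, tolerance = 1.5)

  one <- annotation_track("inspiration", 0.5, 1.0)
  expect_warning(measure_snr(audio_clip(x2, sr), one), "one annotated")
})
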