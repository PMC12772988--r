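test_that("periodicity features match a direct evaluation of the lagged sum", {
  fr <- 10
  t <- (0:299) / fr
  x <- cos(2 * pi * t / 4)                      # 4 s period
  X <- frame_features(matrix(x, 1), fr, "audio")
  Pm <- compute_periodicity(X, max_lag_s = 10, smooth_s = 0)
  # brute-force oracle at every lag
  expected <- vapply(1:100, function(l) naive_periodicity(x, l), numeric(1))
  expect_equal(Pm$P[1, ], expected, tolerance = 1e-12)
  # maximal near the period, minimal near the half-period (minima/maxima
  # recur at every half/full multiple, so search below one period)
  in_range <- Pm$lags_s <= 4.2
  capped <- Pm$P[1, ]
  capped[!in_range] <- 0
  expect_equal(Pm$lags_s[which.max(capped)], 4, tolerance = 0.11)
  expect_equal(Pm$lags_s[which.min(capped)], 2, tolerance = 0.11)
})

test_that("degenerate periodicity inputs behave as documented", {
  fr <- 10
  X <- frame_features(rbind(rep(5, 300), sin((0:299) / 3)), fr, "audio")
  Pm <- compute_periodicity(X, max_lag_s = 5, smooth_s = 0)
  expect_true(all(Pm$P[1, ] == 0))              # constant channel
  # lag-0 autocovariance (computed on the centred series) is the MSD
  x <- X$values[2, ]
  expect_equal(naive_periodicity(x, 0), mean((x - mean(x))^2))
  expect_error(compute_periodicity(X, max_lag_s = 20), "too short")
})

test_that("channel variance ranks periodic channels first", {
  Pm <- structure(list(P = rbind(rep(3, 50), sin(1:50)),
                       lags_s = (1:50) / 10, frame_rate = 10),
                  class = "periodicity_matrix")
  rk <- channel_variance(Pm)
  expect_equal(rk$V[1], 0)
  expect_identical(rk$order[1], 2L)

  g <- synth_video_features(duration_s = 40, true_rate = 20, n_periodic = 1,
                            noise_sd = 0.3, drift_slope = 0, seed = 21)
  rk <- channel_variance(compute_periodicity(g$features, max_lag_s = 8))
  expect_identical(rk$order[1], g$periodic_channels[1])
})

test_that("aggregation is linear and respects the prior", {
  Pm <- structure(list(P = rbind(sin(1:40), sin(1:40), cos(1:40)),
                       lags_s = (1:40) / 4, frame_rate = 4),
                  class = "periodicity_matrix")
  rk <- channel_variance(Pm)
  w <- bipf(Pm$lags_s)
  a1 <- aggregate_periodicity(Pm, rk, 1, w)
  expect_equal(a1$curve, w * Pm$P[rk$order[1], ])
  flat <- aggregate_periodicity(Pm, rk, 3, rep(1, 40))
  expect_equal(flat$curve, colSums(Pm$P))
  # two identical channels double the curve
  two <- aggregate_periodicity(Pm, rk, 2, w)
  expect_equal(two$curve, 2 * a1$curve)
})

test_that("the breathing-interval prior is scale-free and unimodal", {
  lags <- seq(0.5, 10, by = 0.01)
  w <- bipf(lags)
  expect_equal(max(w), 1)
  expect_true(all(w >= 0))
  expect_equal(lags[which.max(w)], 3, tolerance = 0.02)
  expect_identical(bipf(lags, shape = "flat"), rep(1, length(lags)))
})

test_that("first local maximum follows the pinned neighbour rule", {
  curve <- c(0, 1, 3, 2, 4, 1)
  expect_identical(first_local_max(curve, 1:6, 1, 6), 3L)
  expect_identical(first_local_max(6:1, 1:6, 1, 6), NA_integer_)
  # plateau resolves to its first index
  expect_identical(first_local_max(c(0, 2, 2, 1), 1:4, 1, 4), 2L)
  # cosine curve with flat prior peaks at the period
  lags <- (1:100) / 10
  curve <- cos(2 * pi * lags / 4)
  i <- first_local_max(curve, lags, 1, 10)
  expect_equal(lags[i], 4, tolerance = 0.11)
  expect_error(first_local_max(curve, lags, 5, 2), "min_lag_s")
})

test_that("trough and positivity guards reject shoulder artifacts", {
  # decaying shoulder times a rising prior: spurious bump before any trough
  lags <- (1:100) / 10
  shoulder <- 4 * pmax(0, 1 - lags / 2.2) + cos(2 * pi * lags / 5)
  curve <- shoulder * bipf(lags)
  bare <- first_local_max(curve, lags, 1, 10)
  guarded <- first_local_max(curve, lags, 1, 10, after_trough = TRUE)
  expect_lt(lags[bare], 3)                      # artifact on the shoulder
  expect_equal(lags[guarded], 4.7, tolerance = 0.35)  # prior-shifted peak
  # a negative wiggle is not a periodicity peak
  curve <- c(-1, -0.5, -0.6, 0.5, 2, 0.5)
  expect_identical(first_local_max(curve, 1:6, 1, 6, require_positive = TRUE),
                   5L)
  expect_identical(first_local_max(curve, 1:6, 1, 6), 2L)
})

test_that("rate follows R = 60 / l_max", {
  fr <- 29.9
  t <- (0:(60 * fr)) / fr
  for (p in c(2, 4)) {
    X <- frame_features(matrix(cos(2 * pi * t / p), 1), fr, "video")
    est <- estimate_rr_autocorr(X, k = 1, prior_shape = "flat")
    expect_equal(est$l_max_s, p, tolerance = 0.05)
    expect_equal(est$rate, 60 / est$l_max_s)
  }
})

test_that("pipeline with k = all and flat prior matches a brute-force oracle", {
  set.seed(9)
  fr <- 10
  t <- (0:299) / fr
  X <- rbind(cos(2 * pi * t / 3.5) + rnorm(300, sd = 0.05),
             sin(2 * pi * t / 3.5) + rnorm(300, sd = 0.05),
             rnorm(300, sd = 0.3))
  ff <- frame_features(X, fr, "video")
  est <- estimate_rr_autocorr(ff, k = 3, prior_shape = "flat", smooth_s = 0)

  # independent oracle: direct lagged sums, variances, sum, first peak after
  # the first trough
  L <- 100
  P <- t(vapply(1:3, function(i)
    vapply(1:L, function(l) naive_periodicity(X[i, ], l), numeric(1)),
    numeric(L)))
  V <- apply(P, 1, function(r) mean((r - mean(r))^2))
  curve <- colSums(P[order(-V), , drop = FALSE])
  trough <- which(diff(sign(diff(curve))) > 0)[1] + 1L
  peaks <- which(diff(sign(diff(curve))) < 0) + 1L
  peaks <- peaks[peaks > trough & (peaks / fr) >= 1 & curve[peaks] > 0]
  l_max <- peaks[1] / fr
  expect_equal(est$l_max_s, l_max)
  expect_equal(est$rate, 60 / l_max)
})

test_that("the estimate is invariant to channel order and channel scale", {
  g <- synth_video_features(duration_s = 40, true_rate = 18, seed = 31)
  base <- estimate_rr_autocorr(g$features, k = 10)
  perm <- sample(84)
  shuffled <- frame_features(g$features$values[perm, ], g$features$frame_rate,
                             "video")
  expect_equal(estimate_rr_autocorr(shuffled, k = 10)$rate, base$rate)

  # with standardization on, per-channel affine rescaling changes nothing
  std <- estimate_rr_autocorr(g$features, k = 10, standardize = TRUE)
  scaled <- g$features$values * runif(84, 0.5, 2) + runif(84, -5, 5)
  ff <- frame_features(scaled, g$features$frame_rate, "video")
  expect_equal(estimate_rr_autocorr(ff, k = 10, standardize = TRUE)$rate,
               std$rate)
})

test_that("noiseless periodic input is recovered to within one lag step", {
  fr <- 29.9
  for (p in c(2, 3.1, 4.5, 6)) {
    g <- synth_video_features(duration_s = 60, true_rate = 60 / p,
                              n_periodic = 84, noise_sd = 0, drift_slope = 0,
                              frame_rate = fr, seed = 2)
    est <- estimate_rr_autocorr(g$features, k = 84, prior_shape = "flat")
    lag_err <- 60 / p - 60 / (p + 1 / fr)
    expect_lte(abs(est$rate - 60 / p), lag_err + 0.15)
  }
})

test_that("a flat curve falls back to the flagged global maximum", {
  X <- frame_features(matrix(rep(c(0.5, 0.5), 300), 1), 10, "audio")
  est <- estimate_rr_autocorr(X, k = 1)
  expect_true(est$diagnostics$fallback)
})
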