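test_that("derived frame bounds and initial probabilities follow the model", {
  p <- hsmm_params(frame_rate = 1, B_min = 10, B_max = 30)
  expect_identical(p$F_Bmax, 2L)
  expect_identical(p$F_Bmin, 6L)
  # gap-uniform weight over admissible gaps
  expect_equal(1 / (p$F_Bmin - p$F_Bmax + 1), 1 / 5)

  # out-of-range gap has zero probability
  expect_identical(initial_prob(1, 9, p, 20), 0)
  expect_identical(initial_prob(1, 2, p, 20), 0)

  # probabilities sum to 1 over the enumerated admissible states
  total <- 0
  for (i in 1:20) for (j in 1:20) total <- total + initial_prob(i, j, p, 20)
  expect_equal(total, 1)
})

test_that("transition probabilities are a renormalized Gaussian in the gap", {
  p <- hsmm_params(frame_rate = 1, B_min = 6, B_max = 20, sigma_s = 2)
  T_frames <- 100L
  gaps <- p$F_Bmax:p$F_Bmin
  # rows sum to 1 over admissible next states
  row <- vapply(gaps, function(g) transition_prob(c(10, 16), c(16, 16 + g),
                                                  p, T_frames), numeric(1))
  expect_equal(sum(row), 1)
  # mode at k - j == j - i, symmetric about it
  expect_identical(which.max(row), which(gaps == 6L))
  expect_equal(transition_prob(c(10, 16), c(16, 21), p, T_frames),
               transition_prob(c(10, 16), c(16, 23), p, T_frames))

  expect_error(transition_prob(c(10, 16), c(15, 20), p, T_frames),
               "middle breath")

  # vanishing variance concentrates all mass on gap repetition
  tight <- hsmm_params(frame_rate = 1, B_min = 6, B_max = 20, sigma_s = 0.1)
  expect_gte(transition_prob(c(10, 16), c(16, 22), tight, T_frames), 0.99)
})

test_that("emission probability is the product of boundary probabilities", {
  bb <- boundary_probs(c(1, 0, 0.5, 0.2), 1)
  expect_identical(emission_prob(1, 1, bb), 1)
  expect_identical(emission_prob(2, 3, bb), 0)
  expect_equal(emission_prob(3, 4, bb), 0.1)
  expect_error(emission_prob(1, 9, bb), "out of range")
})

test_that("depth-1 decoding is the argmax of initial times emission", {
  p <- hsmm_params(frame_rate = 1, B_min = 10, B_max = 30, Q = 1)
  set.seed(31)
  bb <- boundary_probs(runif(15, 0.05, 1), 1)
  got <- viterbi_decode(bb, p, Q = 1)
  # closed-form enumeration
  best <- -Inf; best_ij <- NULL
  for (i in 1:14) for (j in (i + 1):15) {
    v <- initial_prob(i, j, p, 15) * emission_prob(i, j, bb)
    if (v > best) { best <- v; best_ij <- c(i, j) }
  }
  expect_identical(got$breath_times, as.integer(best_ij))
  expect_equal(got$score, log(best))
})

test_that("an impulse train is decoded exactly", {
  p1 <- rep(1e-3, 12)
  p1[c(3, 6, 9, 12)] <- 0.9
  bb <- boundary_probs(p1, 1)
  p <- hsmm_params(frame_rate = 1, B_min = 10, B_max = 30)
  got <- viterbi_decode(bb, p, Q = 3)
  expect_identical(got$breath_times, c(3L, 6L, 9L, 12L))
  oracle <- brute_force_decode(bb, p, Q = 3)
  expect_identical(oracle$breath_times, got$breath_times)
  expect_equal(oracle$score, got$score, tolerance = 1e-9)
})

test_that("decoder and exhaustive oracle agree on random instances", {
  p <- hsmm_params(frame_rate = 1, B_min = 10, B_max = 30, sigma_s = 1.5)
  set.seed(99)
  for (r in 1:25) {
    bb <- boundary_probs(runif(20, 0.01, 1), 1)
    v <- viterbi_decode(bb, p, Q = 3)
    o <- brute_force_decode(bb, p, Q = 3)
    expect_identical(v$breath_times, o$breath_times)
    expect_equal(v$score, o$score, tolerance = 1e-9)
  }
  # ties (uniform emissions) resolve identically in both implementations
  bbu <- boundary_probs(rep(0.5, 18), 1)
  pu <- hsmm_params(frame_rate = 1, B_min = 10, B_max = 30, sigma_s = 5)
  v <- viterbi_decode(bbu, pu, Q = 2)
  o <- brute_force_decode(bbu, pu, Q = 2)
  expect_identical(v$breath_times, o$breath_times)
  expect_equal(v$score, o$score, tolerance = 1e-9)

  expect_error(brute_force_decode(boundary_probs(rep(0.5, 40), 1), pu, 2),
               "guard")
})

test_that("pruning safety: the wide-range decode dominates the narrow path", {
  # widening [B_min, B_max] rescales the normalized probabilities, so raw
  # scores are not comparable across bounds; the safety property is that the
  # narrow optimum stays admissible in the wider space and the decoder's
  # wide optimum scores at least as well as it under the wide model
  score_path <- function(times, p, bb, T_frames) {
    s <- log(initial_prob(times[1], times[2], p, T_frames)) +
      log(emission_prob(times[1], times[2], bb))
    for (q in seq_len(length(times) - 2L)) {
      s <- s + log(transition_prob(times[q:(q + 1)], times[(q + 1):(q + 2)],
                                   p, T_frames)) +
        log(emission_prob(times[q + 1], times[q + 2], bb))
    }
    s
  }
  set.seed(17)
  bb <- boundary_probs(runif(60, 0.05, 1), 1)
  narrow <- hsmm_params(frame_rate = 1, B_min = 10, B_max = 30)
  wide <- hsmm_params(frame_rate = 1, B_min = 8, B_max = 40)
  path_n <- viterbi_decode(bb, narrow, Q = 4)$breath_times
  dec_w <- viterbi_decode(bb, wide, Q = 4)
  expect_equal(dec_w$score, score_path(dec_w$breath_times, wide, bb, 60),
               tolerance = 1e-9)
  expect_gte(dec_w$score + 1e-9, score_path(path_n, wide, bb, 60))
})

test_that("rates from alignments are 60 over the mean gap", {
  a <- structure(list(breath_times = c(1L, 4L, 7L, 10L), score = 0, Q = 3L,
                      frame_rate = 1), class = "breath_alignment")
  expect_equal(rr_from_alignment(a)$rate, 20)
  a$breath_times <- c(1L, 3L)
  expect_equal(rr_from_alignment(a)$rate, 30)
  # jittered gaps average out
  a$breath_times <- as.integer(cumsum(c(1, 25, 30, 35)))
  expect_equal(rr_from_alignment(a, frame_rate = 10)$rate, 20)
  a$breath_times <- 5L
  expect_error(rr_from_alignment(a), "at least two")
})

test_that("rates are recovered from noisy synthetic boundary series", {
  errs <- vapply(1:8, function(seed) {
    s <- synth_boundary_probs(duration_s = 30, true_rate = 20,
                              interval_jitter_sd = 0.2, seed = seed)
    realized <- 60 / (mean(diff(s$boundary_frames)) / s$p$frame_rate)
    abs(estimate_rr_hsmm(s$p)$rate - realized)
  }, numeric(1))
  expect_lte(median(errs), 1.5)
})
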