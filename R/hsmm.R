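#' HSMM parameters for breath alignment
#'
#' The model's states are pairs of adjacent breath timesteps `(i, j)`; the
#' gap `j - i` (an inter-breath interval in frames) is restricted to the
#' range implied by the admissible rates: `F_Bmax = round(frame_rate *
#' 60/B_max)` frames at the fastest rate up to `F_Bmin = round(frame_rate *
#' 60/B_min)` at the slowest. The transition variance is configured in
#' seconds and converted to frames^2 (`sigma2 = (sigma_s * frame_rate)^2`).
#'
#' @param frame_rate Frames per second of the boundary-probability series.
#' @param B_min,B_max Slowest / fastest admissible rates in breaths/min.
#' @param sigma_s Transition standard deviation in seconds.
#' @param Q Trellis depth (number of states = inter-breath transitions), or
#'   `"auto"` to select by per-transition normalized log score.
#' @return An `hsmm_params` list, including the derived `F_Bmax`, `F_Bmin`
#'   and `i_max` (latest admissible first-breath frame, one maximal
#'   interval).
#' @export
hsmm_params <- function(frame_rate, B_min = 6, B_max = 60, sigma_s = 0.5,
                        Q = "auto") {
  if (B_min <= 0 || B_min >= B_max) stop("need 0 < B_min < B_max")
  F_Bmax <- as.integer(round(frame_rate * 60 / B_max))
  F_Bmin <- as.integer(round(frame_rate * 60 / B_min))
  if (F_Bmax < 1L || F_Bmax >= F_Bmin)
    stop("degenerate gap range: F_Bmax = ", F_Bmax, ", F_Bmin = ", F_Bmin)
  structure(list(frame_rate = frame_rate, B_min = B_min, B_max = B_max,
                 sigma_s = sigma_s, sigma2 = (sigma_s * frame_rate)^2,
                 Q = Q, F_Bmax = F_Bmax, F_Bmin = F_Bmin, i_max = F_Bmin),
            class = "hsmm_params")
}

# shared model arithmetic (also used by the brute-force oracle's caller)
.hsmm_n0 <- function(p, T_frames) {
  n0 <- 0L
  for (i in seq_len(min(p$i_max, T_frames))) {
    n0 <- n0 + sum(i + p$F_Bmax:p$F_Bmin <= T_frames)
  }
  n0
}

.hsmm_gauss_log <- function(d, sigma2) {
  -0.5 * log(2 * pi * sigma2) - d^2 / (2 * sigma2)
}

# log transition normalizer out of state (i, j): sum over admissible k
.hsmm_zlog <- function(p, j, gap_prev, T_frames) {
  ks <- (j + p$F_Bmax):min(j + p$F_Bmin, T_frames)
  ks <- ks[ks > j]
  if (!length(ks)) return(-Inf)
  v <- .hsmm_gauss_log(ks - j - gap_prev, p$sigma2)
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Initial state probability
#'
#' Uniform over the admissible initial states: gap `j - i` within
#' `[F_Bmax, F_Bmin]`, first breath within one maximal interval
#' (`i <= F_Bmin`), and `j <= T`; zero otherwise. Probabilities sum to 1
#' over the enumerated admissible states.
#'
#' @param i,j Breath timesteps (1-based frames), `i < j`.
#' @param p An [hsmm_params()].
#' @param T_frames Series length in frames.
#' @return A probability.
#' @export
initial_prob <- function(i, j, p, T_frames) {
  stopifnot(inherits(p, "hsmm_params"))
  gap <- j - i
  if (i < 1L || j > T_frames || gap < p$F_Bmax || gap > p$F_Bmin ||
      i > p$i_max) return(0)
  1 / .hsmm_n0(p, T_frames)
}

#' Transition probability
#'
#' From state `(i, j)` to state `(j, k)` (the middle breath must be shared):
#' a Gaussian in the new gap centred on the previous gap,
#' `N(k - j; mu = j - i, sigma2)`, renormalized over the admissible `k`
#' reachable from `j` so each state's outgoing transitions sum to 1.
#'
#' @param prev,nxt Length-2 integer vectors `(i, j)` and `(j, k)`.
#' @param p An [hsmm_params()].
#' @param T_frames Series length in frames.
#' @return A probability.
#' @export
transition_prob <- function(prev, nxt, p, T_frames) {
  stopifnot(inherits(p, "hsmm_params"))
  if (prev[2L] != nxt[1L]) stop("mismatched middle breath index")
  gi <- prev[2L] - prev[1L]
  gk <- nxt[2L] - nxt[1L]
  if (gk < p$F_Bmax || gk > p$F_Bmin || nxt[2L] > T_frames) return(0)
  exp(.hsmm_gauss_log(gk - gi, p$sigma2) -
      .hsmm_zlog(p, prev[2L], gi, T_frames))
}

#' Emission probability
#'
#' The probability of a state `(i, j)` is the product of the framewise
#' boundary probabilities at both of its breath timesteps,
#' `b_ij = BB(i) * BB(j)`.
#'
#' @param i,j Breath timesteps (1-based frames).
#' @param bb A [boundary_probs()].
#' @return A probability.
#' @export
emission_prob <- function(i, j, bb) {
  stopifnot(inherits(bb, "boundary_probs"))
  n <- length(bb$p1)
  if (i < 1L || j < 1L || i > n || j > n) stop("timestep out of range")
  bb$p1[i] * bb$p1[j]
}

#' Viterbi breath alignment
#'
#' Decodes the most probable sequence of adjacent-breath states from a
#' boundary-probability series, in log space, over the pruned state space of
#' admissible gaps. The recursion is run backward (maximum score-to-go) and
#' the path reconstructed forward, which makes the documented tie-break
#' exact: among score-optimal paths the lexicographically smallest
#' breath-time sequence is returned. With `Q = "auto"` the per-transition
#' normalized log score `delta/Q` is evaluated for every feasible depth up
#' to `q_cap` and the best kept (ties to the smaller depth).
#'
#' @param bb A [boundary_probs()].
#' @param p An [hsmm_params()] (`frame_rate` should match `bb`).
#' @param Q Depth override; default `p$Q`. Either a positive integer, a
#'   vector of candidate depths, or `"auto"`.
#' @param q_cap Largest depth examined under `"auto"`.
#' @param tol Score tolerance used when grouping ties.
#' @return A `breath_alignment`: list with `breath_times` (1-based frames,
#'   length Q+1), `score` (log Viterbi probability), `Q`, `frame_rate`.
#' @export
viterbi_decode <- function(bb, p, Q = p$Q, q_cap = 64L, tol = 1e-9) {
  stopifnot(inherits(bb, "boundary_probs"), inherits(p, "hsmm_params"))
  T_frames <- length(bb$p1)
  if (T_frames < p$F_Bmax + 1L)
    stop("series shorter than one admissible breath interval")
  if (identical(Q, "auto")) {
    qmax <- min(as.integer(q_cap), (T_frames - 1L) %/% p$F_Bmax)
    if (qmax < 1L) stop("no admissible sequence fits in the series")
    Q <- seq_len(qmax)
  }
  Q <- as.integer(Q)
  if (any(Q < 1L)) stop("Q must be positive")
  res <- .viterbi_cpp(log(bb$p1), p$F_Bmax, p$F_Bmin, p$sigma2,
                      sort(Q), p$i_max, tol)
  structure(list(breath_times = as.integer(res$breath_times),
                 score = res$score, Q = res$Q, frame_rate = p$frame_rate),
            class = "breath_alignment")
}

#' @export
print.breath_alignment <- function(x, ...) {
  cat(sprintf("<breath_alignment> %d breaths, log score %.3f\n",
              length(x$breath_times), x$score))
  invisible(x)
}

#' Exhaustive decoding oracle
#'
#' Enumerates every admissible breath sequence of depth `Q` (guarded to tiny
#' problems), scoring with the same model definition as [viterbi_decode()]
#' but by direct summation along each path, and returns the best; sequences
#' are enumerated in lexicographic order and the first within-tolerance
#' optimum kept, so ties resolve identically to the decoder.
#'
#' @param bb A [boundary_probs()].
#' @param p An [hsmm_params()].
#' @param Q Depth (number of states; `Q + 1` breaths).
#' @param tol Tie tolerance on log scores.
#' @return A `breath_alignment`, or an error if no admissible sequence
#'   exists.
#' @export
brute_force_decode <- function(bb, p, Q, tol = 1e-9) {
  stopifnot(inherits(bb, "boundary_probs"), inherits(p, "hsmm_params"))
  T_frames <- length(bb$p1)
  if (T_frames > 25L || Q > 4L)
    stop("combinatorial guard: T <= 25 and Q <= 4")
  logbb <- log(bb$p1)
  logpi <- -log(.hsmm_n0(p, T_frames))
  gaps <- p$F_Bmax:p$F_Bmin
  best <- list(score = -Inf, times = NULL)
  score_path <- function(times) {
    s <- logpi + logbb[times[1L]] + logbb[times[2L]]
    for (q in seq_len(length(times) - 2L)) {
      j <- times[q + 1L]; k <- times[q + 2L]
      gi <- j - times[q]
      s <- s + .hsmm_gauss_log((k - j) - gi, p$sigma2) -
        .hsmm_zlog(p, j, gi, T_frames) + logbb[j] + logbb[k]
    }
    s
  }
  recurse <- function(times) {
    if (length(times) == Q + 1L) {
      s <- score_path(times)
      if (s > best$score + tol) best <<- list(score = s, times = times)
      return(invisible())
    }
    last <- times[length(times)]
    for (g in gaps) {
      nxt <- last + g
      if (nxt <= T_frames) recurse(c(times, nxt))
    }
  }
  for (i in seq_len(min(p$i_max, T_frames))) recurse(i)
  if (is.null(best$times)) stop("no admissible sequence of depth ", Q)
  structure(list(breath_times = as.integer(best$times), score = best$score,
                 Q = as.integer(Q), frame_rate = p$frame_rate),
            class = "breath_alignment")
}

#' Respiratory rate from a breath alignment
#'
#' The rate is 60 over the mean inter-breath interval (in seconds) of the
#' decoded breath times.
#'
#' @param a A `breath_alignment`.
#' @param frame_rate Frames per second; defaults to the alignment's.
#' @return An [rr_estimate()] with method `"bb-hsmm"`.
#' @export
rr_from_alignment <- function(a, frame_rate = a$frame_rate) {
  stopifnot(inherits(a, "breath_alignment"))
  if (length(a$breath_times) < 2L) stop("need at least two breath times")
  gbar <- mean(diff(a$breath_times)) / frame_rate
  rr_estimate(rate = 60 / gbar, method = "bb-hsmm", l_max_s = gbar,
              diagnostics = list(breath_times = a$breath_times,
                                 score = a$score, Q = a$Q))
}

#' End-to-end HSMM rate estimate
#'
#' Convenience composition of [viterbi_decode()] and [rr_from_alignment()].
#'
#' @param bb A [boundary_probs()].
#' @param p An [hsmm_params()]; defaults to [hsmm_params()] at the series'
#'   frame rate.
#' @param ... Passed to [viterbi_decode()].
#' @return An [rr_estimate()].
#' @export
estimate_rr_hsmm <- function(bb, p = hsmm_params(bb$frame_rate), ...) {
  rr_from_alignment(viterbi_decode(bb, p, ...))
}
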