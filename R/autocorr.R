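#' Per-channel periodicity features
#'
#' For each channel i and integer frame lag l = 1..L, computes the
#' mean-centred lagged product
#' \deqn{P_{i,l} = \frac{1}{M-l+1} \sum_{n=0}^{M-l} (X_{i,n}-\bar X_i)(X_{i,n+l}-\bar X_i)}
#' with frames indexed 0..M (M = frame count - 1), i.e. the biased-window
#' autocovariance averaged over the valid pairs at each lag. The matrix is
#' then smoothed along the lag axis with a zero-phase moving average
#' (`smooth_s` seconds of lag; window truncated at the edges). Lags are
#' integer frames internally and converted to seconds by the frame rate for
#' reporting.
#'
#' @param X A [frame_features()].
#' @param max_lag_s Largest lag evaluated, in seconds.
#' @param smooth_s Width of the lag-axis moving average in seconds (0
#'   disables smoothing).
#' @param standardize Z-score each channel before the lagged products. Use
#'   for fused features, where audio (log-Mel) and video (pixel-mean)
#'   channels live on incommensurate scales; without it the variance ranking
#'   is dominated by raw channel scale (P scales as c^2, V as c^4 under
#'   channel gain c). Default `"auto"`: on for fused input, off otherwise.
#' @return A `periodicity_matrix`: list with `P` (channels x lags, smoothed),
#'   `lags_s` (lag axis in seconds), `frame_rate`.
#' @export
compute_periodicity <- function(X, max_lag_s = 10, smooth_s = 0.25,
                                standardize = "auto") {
  stopifnot(inherits(X, "frame_features"))
  if (identical(standardize, "auto")) standardize <- X$modality == "fused"
  L <- as.integer(round(max_lag_s * X$frame_rate))
  n <- ncol(X$values)
  if (n < 2L * L)
    stop("recording too short: need at least 2*max_lag = ", 2L * L,
         " frames, have ", n)
  Xc <- X$values - rowMeans(X$values)
  if (standardize) {
    s <- sqrt(rowMeans(Xc^2))
    s[s == 0] <- 1
    Xc <- Xc / s
  }
  P <- matrix(0, nrow(Xc), L)
  for (l in seq_len(L)) {
    m <- n - l
    P[, l] <- rowSums(Xc[, 1:m, drop = FALSE] *
                      Xc[, (l + 1):n, drop = FALSE]) / m
  }
  if (smooth_s > 0) {
    w <- as.integer(round(smooth_s * X$frame_rate))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > 1L) P <- t(apply(P, 1L, .movavg, w = w))
  }
  structure(list(P = P, lags_s = seq_len(L) / X$frame_rate,
                 frame_rate = X$frame_rate),
            class = "periodicity_matrix")
}

# centred moving average; window shrinks symmetrically-as-available at edges
.movavg <- function(x, w) {
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Rank channels by periodicity-feature variance
#'
#' \deqn{V_i = \frac{1}{N} \sum_{l=1}^{N} (P_{i,l} - \bar P_i)^2}
#' Periodic channels oscillate along the lag axis (high P at multiples of the
#' period, low in between) and therefore have large V; aperiodic channels are
#' flat. Ties are broken by lower channel index.
#'
#' @param Pm A `periodicity_matrix` from [compute_periodicity()].
#' @return A `channel_ranking`: list with `V` (per-channel variance) and
#'   `order` (channel indices sorted by decreasing V).
#' @export
channel_variance <- function(Pm) {
  stopifnot(inherits(Pm, "periodicity_matrix"))
  if (ncol(Pm$P) < 2L) stop("need at least 2 lags")
  V <- rowMeans((Pm$P - rowMeans(Pm$P))^2)
  structure(list(V = V, order = order(-V, seq_along(V))),
            class = "channel_ranking")
}

#' Breathing-interval prior (BIPF)
#'
#' A scale-free weight over candidate breath intervals, concentrating mass at
#' physiologically typical adult intervals and making very high rates less
#' likely. The default is log-normal-shaped in the lag,
#' `w(l) = exp(-(log l - log mode)^2 / (2 sigma_log^2))`, normalized to
#' maximum 1; `shape = "flat"` gives `w == 1` everywhere.
#'
#' @param lags_s Lag axis in seconds.
#' @param shape `"lognormal"` or `"flat"`.
#' @param mode_s Mode of the prior in seconds (default 3 s, i.e. 20
#'   breaths/min).
#' @param sigma_log Log-scale spread (default 0.5).
#' @return Numeric weight vector over `lags_s`, max 1.
#' @export
bipf <- function(lags_s, shape = c("lognormal", "flat"), mode_s = 3,
                 sigma_log = 0.5) {
  shape <- match.arg(shape)
  if (shape == "flat") return(rep(1, length(lags_s)))
  w <- exp(-(log(lags_s) - log(mode_s))^2 / (2 * sigma_log^2))
  w / max(w)
}

#' Aggregate top-k periodicity channels under a prior
#'
#' `curve(l) = w(l) * sum over the top-k ranked channels of P_{i,l}`.
#'
#' @param Pm A `periodicity_matrix`.
#' @param ranking A `channel_ranking` from [channel_variance()].
#' @param k Number of channels to keep, `1 <= k <= channels`.
#' @param prior Weight vector over lags (e.g. from [bipf()]); recycled
#'   scalars allowed.
#' @return List with `curve` (lag-indexed numeric), `lags_s`, `selected`
#'   (channel indices used).
#' @export
aggregate_periodicity <- function(Pm, ranking, k,
                                  prior = bipf(Pm$lags_s)) {
  stopifnot(inherits(Pm, "periodicity_matrix"),
            inherits(ranking, "channel_ranking"))
  if (k < 1L || k > nrow(Pm$P)) stop("k must be in [1, channels]")
  sel <- ranking$order[seq_len(k)]
  curve <- prior * colSums(Pm$P[sel, , drop = FALSE])
  list(curve = as.numeric(curve), lags_s = Pm$lags_s, selected = sel)
}

#' First local maximum of a lag curve
#'
#' Returns the smallest lag l in `[min_lag_s, max_lag_s]` with
#' `curve(l-1) < curve(l) >= curve(l+1)` (neighbours taken on the full curve
#' support); a plateau resolves to its first index.
#'
#' @param curve Numeric values over `lags_s`.
#' @param lags_s Lag axis in seconds.
#' @param min_lag_s,max_lag_s Search range in seconds.
#' @param require_positive Only accept local maxima with `curve > 0`. A
#'   positive autocovariance peak signals self-similarity at that lag; a
#'   "maximum" at negative autocovariance is a wiggle in an anti-correlated
#'   trough, not a periodicity peak, and jittered breath trains routinely
#'   produce such shoulder wiggles below the true interval. Off by default
#'   (the bare textbook rule); the rate estimators turn it on.
#' @param after_trough Only accept local maxima that follow a local minimum
#'   somewhere earlier on the curve (scanned from the first lag, also below
#'   `min_lag_s`). An autocovariance decays from its zero-lag variance
#'   before the first genuine periodicity peak, and an interval prior with a
#'   rising edge can otherwise carve a spurious "first maximum" out of that
#'   decaying shoulder. Off by default; the rate estimators turn it on.
#' @return Index into `lags_s` of the first local maximum, or `NA_integer_`
#'   if none exists in range.
#' @export
first_local_max <- function(curve, lags_s, min_lag_s = 1, max_lag_s = 10,
                            require_positive = FALSE, after_trough = FALSE) {
  if (min_lag_s >= max_lag_s) stop("min_lag_s must be < max_lag_s")
  n <- length(curve)
  if (after_trough) {
    interior <- 2L:(n - 1L)
    mins <- interior[curve[interior - 1L] > curve[interior] &
                     curve[interior] <= curve[interior + 1L]]
    first_trough <- if (length(mins)) mins[1L] else Inf
  } else first_trough <- -Inf
  cand <- which(lags_s >= min_lag_s & lags_s <= max_lag_s)
  cand <- cand[cand > 1L & cand < n]
  for (i in cand) {
    if (i > first_trough &&
        curve[i - 1L] < curve[i] && curve[i] >= curve[i + 1L] &&
        (!require_positive || curve[i] > 0))
      return(i)
  }
  NA_integer_
}

#' Respiratory rate by periodicity autocorrelation
#'
#' The end-to-end signal-processing estimator: periodicity features per
#' channel, variance ranking, top-k aggregation under a breathing-interval
#' prior, first-local-maximum lag, and `R = 60 / l_max` with `l_max` in
#' seconds. If no local maximum exists in the search range the estimator
#' falls back to the global maximum of the prior-weighted curve in range and
#' flags the estimate (`diagnostics$fallback`).
#'
#' @param X A [frame_features()] (any modality; fused input is standardized
#'   per channel by default, see [compute_periodicity()]).
#' @param k Number of top-variance channels to aggregate.
#' @param prior_shape,prior_mode_s,prior_sigma_log Prior settings; see
#'   [bipf()].
#' @param min_lag_s,max_lag_s Lag search range in seconds (defaults 1 s /
#'   10 s, i.e. 60 down to 6 breaths/min).
#' @param smooth_s,standardize Passed to [compute_periodicity()].
#' @return An [rr_estimate()] with method `"autocorr-<modality>"`.
#' @export
estimate_rr_autocorr <- function(X, k = 30L,
                                 prior_shape = c("lognormal", "flat"),
                                 prior_mode_s = 3, prior_sigma_log = 0.5,
                                 min_lag_s = 1, max_lag_s = 10,
                                 smooth_s = 0.25, standardize = "auto") {
  prior_shape <- match.arg(prior_shape)
  k <- min(as.integer(k), nrow(X$values))
  Pm <- compute_periodicity(X, max_lag_s = max_lag_s, smooth_s = smooth_s,
                            standardize = standardize)
  rk <- channel_variance(Pm)
  w <- bipf(Pm$lags_s, prior_shape, prior_mode_s, prior_sigma_log)
  ag <- aggregate_periodicity(Pm, rk, k, w)
  i <- first_local_max(ag$curve, ag$lags_s, min_lag_s, max_lag_s,
                       require_positive = TRUE, after_trough = TRUE)
  fallback <- is.na(i)
  if (fallback) {
    in_range <- which(ag$lags_s >= min_lag_s & ag$lags_s <= max_lag_s)
    if (!length(in_range)) stop("no lags in search range")
    i <- in_range[which.max(ag$curve[in_range])]
  }
  l_max <- ag$lags_s[i]
  rr_estimate(rate = 60 / l_max, method = paste0("autocorr-", X$modality),
              l_max_s = l_max,
              diagnostics = list(selected = ag$selected, curve = ag$curve,
                                 lags_s = ag$lags_s, V = rk$V,
                                 fallback = fallback))
}

#' Respiratory-rate estimate container
#'
#' @param rate Breaths per minute.
#' @param method Method tag (e.g. `"autocorr-video"`, `"bb"`, `"bb-hsmm"`).
#' @param l_max_s Chosen periodicity lag in seconds, if applicable.
#' @param diagnostics Free-form list (selected channels, curves, alignment,
#'   fallback flags).
#' @return An object of class `rr_estimate`.
#' @export
rr_estimate <- function(rate, method, l_max_s = NA_real_,
                        diagnostics = list()) {
  structure(list(rate = rate, method = method, l_max_s = l_max_s,
                 diagnostics = diagnostics),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, ...) {
  cat(sprintf("<rr_estimate> %.2f breaths/min  [%s]", x$rate, x$method))
  if (is.finite(x$l_max_s)) cat(sprintf("  l_max = %.3f s", x$l_max_s))
  if (isTRUE(x$diagnostics$fallback)) cat("  (fallback: global max)")
  cat("\n")
  invisible(x)
}
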