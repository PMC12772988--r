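---
title: "Respiratory rate from breathing audio and chest-motion video: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory rate from breathing audio and chest-motion video: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respirate)
```

respirate estimates respiratory rate (RR, breaths/min) from contactless
recordings by three routes that share one feature representation — a
channels-by-frames matrix sampled near 30 frames/s:

* **Autocorrelation**: a signal-processing estimator over periodicity-ranked
  feature channels, for audio, video, or their fusion.
* **Breathing Boundaries (BB)**: a recurrent neural detector of the frame
  where the louder breath phase begins, followed by autocorrelation on its
  framewise probabilities.
* **BB + HSMM**: the same detector decoded by a hidden semi-Markov model that
  aligns individual breaths and reads the rate off the mean inter-breath
  interval.

This vignette records the models, the tunable parameters and their defaults,
the numerical conventions, what the synthetic generator does and does not
emulate, and the design decisions taken where the method description left the
choice open.

## Feature representation

**Audio.** Recordings are resampled to 8 kHz (polyphase, `signal::resample`)
and converted to a log-Mel spectrogram: window 512 samples, hop 267 samples,
80 Mel bands. The hop is chosen so frames arrive at 8000/267 = 29.96 frames/s,
matching the 29.9 frames/s video rate to within 0.1 frames/s; the two streams
are treated as synchronized (sharing t = 0) and are not resampled onto each
other. Conventions pinned for reproducibility: periodic Hann window, centre
padding by reflection (`T = 1 + floor(n/hop)` frames), power spectrum, HTK
Mel scale over 0–4000 Hz with unnormalized triangular filters, and
`log(power + 1e-10)`. The floor bounds silence at `log(1e-10)` without
affecting breath-level energies.

**Video.** Each frame is cropped to a chest region of interest, converted to
grayscale (BT.601 luma), resized bilinearly to 350 x 600, and averaged over a
7 x 12 grid of 50 x 50 windows, giving 84 channels ordered row-major from the
top-left cell. Per-frame, the mean of all 84 channels equals the mean of the
resized frame; the tests pin this conservation property. The ROI is plain
configuration (default: the full frame). A production system would obtain the
chest box from a pose detector on the first frame; decoupling it keeps the
method testable without an external pose model.

**Fusion** concatenates audio then video channels, truncated to the shorter
stream (164 channels).

## Autocorrelation estimator

For channel $i$ and integer frame lag $l$, with frames indexed $0..M$:

$$P_{i,l} = \frac{1}{M-l+1} \sum_{n=0}^{M-l} (X_{i,n}-\bar X_i)(X_{i,n+l}-\bar X_i)$$

i.e. the mean-centred lagged product averaged over the valid pairs at each
lag. $P$ is smoothed along the lag axis by a zero-phase moving average of
0.25 s width (edge windows shrink). Channels are ranked by

$$V_i = \frac{1}{N}\sum_{l=1}^{N}(P_{i,l}-\bar P_i)^2,$$

large for channels whose $P$ oscillates (periodic motion or sound) and small
for flat ones; ties break to the lower channel index. The top $k$ rows are
summed and multiplied by a breathing-interval prior $w(l)$, and the rate is
$R = 60/l_{\max}$ with $l_{\max}$ the first accepted local maximum of the
weighted curve, in seconds.

Parameters and defaults:

* `k = 30` channels. With 84-channel video and a handful of genuinely
  periodic cells, 30 keeps all informative channels at modest dilution.
* Lag search range 1–10 s (60 down to 6 breaths/min).
* Prior: log-normal-shaped in the lag, mode 3 s (20 breaths/min),
  log-spread 0.5, normalized to maximum 1; a flat prior is available. A
  smooth unimodal weight concentrating mass at typical adult intervals; it
  deliberately makes very short intervals (high rates) less likely, and the
  high-rate experiments below show the consequences.
* Smoothing width 0.25 s of lag.
* Standardization: in fusion mode each channel is z-scored before the lagged
  products. Log-Mel and pixel-mean channels live on incommensurate scales,
  and scaling one channel by $c$ scales its $P$ row by $c^2$ and its $V$ by
  $c^4$, so cross-modality variance ranking is meaningless without it.
  Single-modality input is left on its native scale by default.

**Peak acceptance.** Two guards qualify "first local maximum", both exposed
as options on `first_local_max()` and enabled by the rate estimators:

* *positivity*: a periodicity peak must have positive autocovariance — a
  local "maximum" below zero is a wiggle inside an anti-correlated trough,
  which jittered breath trains routinely produce just below the true
  interval;
* *after the first trough*: the curve decays from its zero-lag variance
  before the first genuine peak, and a prior with a rising edge below its
  mode can otherwise carve a spurious maximum out of that decaying shoulder
  (multiplying a monotone-decaying shoulder by a monotone-rising weight
  yields an interior bump). Scanning for the first local minimum anywhere on
  the curve — including below the lag search floor — and only accepting
  peaks after it is the standard remedy in period estimation.

Without the trough guard, slow synthetic breathing (12–15 breaths/min, whose
cosine-like autocovariance is still positive at 1–1.5 s) is systematically
misread near the prior's rising edge. If no qualifying local maximum exists
the estimator falls back to the global maximum of the weighted curve in range
and flags the estimate (`diagnostics$fallback`).

## Breathing-boundary detector

A boundary is the start frame of whichever phase (inspiration or expiration)
is louder for the subject — mean over same-phase segments of per-segment
average power, ties to inspiration. Each boundary is widened to 10 frames of
class 1 (`[b-5, b+4]`; the even width forces an asymmetric centring, pinned
left-heavy), clipped at clip edges, overlaps taking the union; without
widening the classifier collapses to the majority class.

The model is two bidirectional LSTM layers and two fully-connected layers
with a softmax over {no boundary, boundary}, implemented in RcppArmadillo
with full backpropagation through time. Defaults (all configurable): 16
hidden units per direction, 32 fully-connected units, weighted cross-entropy
with inverse-frequency class weights, Adam at 2e-3 with global gradient-norm
clipping at 5, 8 epochs, one clip per optimizer step. Input features are
z-scored per channel per clip. These sizes are deliberately small: the
synthetic task below is learnable at this scale in well under a minute of CPU
time, and every training knob is exposed for larger corpora.

Determinism: initial weights, the clip order of every epoch, and the
augmentation permutations are all drawn in R from the configured seed before
training starts, so identical seeds give bit-identical models.

**Frequency permutation** shuffles spectrogram channel order (train-time
only, redrawn per clip per epoch). Temporal periodicity survives channel
shuffling, so the augmentation multiplies the effective training set without
changing the labels. A consequence worth noting: under permutation the
network cannot use band identity, so the generator's phase contrast must
survive in permutation-invariant cues (overall level, temporal context) —
one reason the default expiration gain is +6 dB rather than a subtler value.

At inference the class-1 softmax output per frame is the boundary probability
series. Rates follow either by autocorrelation on that series (`k = 1`, the
same prior and guards as above) or by the HSMM.

## HSMM breath alignment

States are pairs of adjacent breath timesteps $(i, j)$ with the gap $j-i$
restricted to $[F_{B_{max}}, F_{B_{min}}]$ frames, the frames-per-breath at
the fastest and slowest admissible rates (defaults 60 and 6 breaths/min).
Scores:

* initial: uniform over admissible first states; the first breath must fall
  within one maximal interval of the start ($i \le F_{B_{min}}$) — the model
  itself constrains only the gap, but some placement rule is required, and
  this one is the weakest assumption that keeps the state count finite;
  probabilities are normalized over the states actually enumerable within
  the series.
* transition from $(i,j)$ to $(j,k)$: Gaussian in the new gap centred on the
  previous gap, $\mathcal N(k-j;\, \mu = j-i,\, \sigma^2)$, renormalized over
  the $k$ admissible from $j$ so every row is a distribution. Renormalization
  is pinned ON: with raw densities the truncation near the end of the series
  silently favours terminal states. $\sigma$ is configured in seconds
  (default 0.5 s) and converted to frames, $\sigma^2 = (0.5 \cdot FR)^2$ —
  the gap variable is in frames, so frames² is the only coherent unit.
* emission of $(i,j)$: the product of the boundary probabilities at both
  timesteps.

Decoding maximizes initial x transitions x emissions over breath sequences of
depth $Q$ in log space, over the pruned state set (admissible gaps only; the
conceptual $T^2$ space is never instantiated). The recursion runs backward —
best score-to-go with $r$ transitions remaining — and the path is
reconstructed forward. Running it in this direction makes the tie-break exact
and cheap: a forward greedy choice over score-optimal continuations returns
the lexicographically smallest breath-time sequence, and the exhaustive
oracle (`brute_force_decode`, guarded to T <= 25, Q <= 4) reproduces it
independently by enumerating sequences in lexicographic order. Score
equality is grouped at 1e-9 in log space.

**Depth selection.** With `Q = "auto"` the decoder evaluates every feasible
depth up to a cap (the score-to-go table is shared across depths, so this
costs one extra scan per depth) and keeps the depth with the best
per-transition normalized log score, ties to the smaller depth. A
median-gap-based guess with ±1 candidates was tried first and discarded: with
a wide admissible range (6–60 breaths/min) the gap midpoint is a poor proxy
for the true interval, and the guess lands far from the optimum at either end
of the rate range. Normalizing by transitions rather than excluding the
depth-independent initial term matters: without amortizing that constant the
criterion degenerates toward minimal depths, which score on emissions alone.

The rate is $60/\bar g$ with $\bar g$ the mean decoded inter-breath interval
in seconds.

## Synthetic data

The generator provides the study conditions for every test; no external data
is needed.

**Breathing audio** (`synth_breath_audio`): alternating
inspiration/expiration bursts — band-passed white noise under raised-cosine
onset/offset envelopes — over a white room-tone floor, at 8 kHz. Inspiration
onsets are spaced $60/\text{rate} + \mathcal N(0, \text{jitter}^2)$ seconds
(default jitter 0.2 s), floored just above the burst durations so breaths
never overlap; expiration starts 45% into each interval. Defaults: bursts
0.6 s / 0.7 s, inspiration band 200–900 Hz, expiration band 1100–2600 Hz,
expiration +6 dB, per-breath level jitter 2 dB (real breathing varies breath
to breath), burst RMS 0.1 over room tone RMS 0.003. The distinct phase bands
reflect the spectral asymmetry of real breath phases; with a single shared
band, every spectral channel would also carry the inspiration-to-expiration
spacing and its autocorrelation peak would compete with the full cycle.
Segment annotations come from the construction, so the supervision pipeline
(louder phase, boundary frames, widened labels) runs on exact ground truth.

**Video grid features** (`synth_video_features`): 84 channels at
29.9 frames/s; a seeded random subset (default 8) carries a sinusoid at the
breathing rate (amplitude 1 intensity unit, random phase), and every channel
carries linear drift (slope uniform in ±0.02 units/s — about ±1 unit/min of
illumination drift on an 8-bit scale, typical of a static indoor scene) plus
Gaussian noise (SD 0.3). The features are synthesized directly at the
feature-matrix level; an actual frame renderer is exercised separately in
the feature-extraction tests.

**Boundary probabilities** (`synth_boundary_probs`): a noisy baseline
(default 0.05 mean, 0.1 frame noise) with Gaussian bumps (height 0.85, SD 2
frames) at jittered breath boundaries, clipped to [0, 1] — emulating a
detector's output directly so the HSMM and the boundary-autocorrelation
route can be studied without a trained network in the loop.

**Noise** (`noise_clip`, `mix_at_snr`): white, pink (Kasdin IIR), or
babble-like (40 random tones with slow random AM), unit RMS, mixed at a
target full-clip power ratio (10·log10(P_signal/P_noise), exact by
construction; `Inf` = clean; short noise is tiled from a seeded offset).
`measure_snr` implements the annotation-based recording-quality measure —
the mean power of the two loudest breath segments over the inter-segment
room tone, in dB; a single-segment track is used alone with a warning.

**What the generator does not emulate.** Real breath sounds are not
stationary band-passed noise: no adventitious sounds (crackles, wheezes), no
speech or coughs, no within-burst pitch structure, no recording-channel
effects. Real chest-motion features are not pure sinusoids plus linear
drift: no posture shifts, occlusions, lighting flicker, or motion outliers.
Passing tests therefore demonstrate correctness of the algorithms and their
qualitative behaviours (channel selection, noise robustness shape, prior
bias at high rates), not clinical accuracy.

## Study problem sizes

The shipped tests and the acceptance script run at these scales, chosen as
the smallest sizes at which each property is stable: rate recovery on 60 s
clips over 12–30 breaths/min with 10 seeds per rate; boundary training on
200 synthetic 30 s clips with a 25-clip held-out set; decoder/oracle
agreement on 100 random 20-frame series; noise robustness on 40 clips of
20 s per SNR level in {clean, 10, 5, 0, −5, −10 dB}.

Two study-condition choices deserve justification:

* The noise-robustness study uses **white** noise on **20 s** clips with
  **irregular breathing** (interval jitter 0.5 s, per-breath level jitter
  6 dB). Pink noise leaves the high-frequency expiration band largely
  unmasked and babble tones mask almost nothing broadband, so neither
  produces graded degradation; white noise is the spectrally matched masker.
  Long clips of metronomic synthetic breathing are unrealistically robust —
  autocorrelation integrates across many identical cycles and shrugs off
  −10 dB — whereas short clips of irregular breathing, which is what
  public breathing-audio corpora of respiratory patients actually contain,
  show the expected shape: little change at 10 dB, degradation appearing by
  5 dB and large errors by −10 dB.
* High-rate comparisons score each method against the **realized** rate of
  the generated series (60 over the mean annotated interval), not the
  nominal setting: with 0.2 s jitter over ~16 intervals the realization
  itself deviates from nominal by about 1 breath/min, which would otherwise
  dominate the method difference being measured.

## Known limitations

* The boundary detector is trained and tested on synthetic material here;
  nothing in this package validates transfer to real corpora.
* The autocorrelation estimator quantizes the rate to the lag grid
  (~0.033 s), noticeable above 30 breaths/min; the prior's low-rate bias
  compounds this at high rates (visible as a systematic ~1.5 breaths/min
  underestimate at 30 breaths/min in the recovery tests). The HSMM route
  does not share this bias — the high-rate experiment asserts exactly that.
* HSMM decoding cost grows with the admissible gap range squared per frame;
  the default 6–60 breaths/min range on minute-long series is seconds of
  CPU, but very long recordings should be windowed.
* `Q = "auto"` assumes the series contains at least one full admissible
  breath sequence; series shorter than one maximal interval plus one frame
  are rejected rather than guessed at.
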