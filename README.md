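# respirate

Contactless respiratory-rate (RR) estimation from breathing **audio** and
chest-motion **video**, for researchers working on camera/microphone-based
vital-sign monitoring (telemedicine, triage, sleep and respiratory studies).

Respiratory rate — breaths per minute, one of the four clinical vital signs —
is usually counted by hand over a minute. This package implements three
estimation routes that need only a consumer microphone or camera:

1. **Autocorrelation over periodicity-ranked channels.** Audio becomes an
   80-band log-Mel spectrogram (8 kHz, window 512, hop 267 ≈ 29.96 frames/s);
   video becomes 84 grid-cell mean intensities (7 × 12 grid of 50 × 50 windows
   on the 350 × 600 chest crop); fusion concatenates both. For each channel
   *i* and frame lag *l*,

       P[i,l] = (1/(M−l+1)) Σₙ (X[i,n] − X̄ᵢ)(X[i,n+l] − X̄ᵢ)

   and channels are ranked by the variance of `P[i,·]` along the lag axis
   (periodic channels oscillate between high and low autocorrelation). The
   top-*k* rows are summed, weighted by a breathing-interval prior, and the
   rate is `R = 60 / l_max` at the first accepted periodicity peak.

2. **Breathing Boundaries (BB).** A bidirectional-LSTM classifier (2 BLSTM +
   2 fully-connected layers, softmax) predicts per frame whether the louder
   breath phase starts there, trained with width-10 widened labels and
   frequency-permutation augmentation; the rate comes from autocorrelation on
   the predicted probability series.

3. **BB + HSMM.** A hidden semi-Markov model whose states are pairs of
   adjacent breath times (i, j): uniform initial probabilities over admissible
   inter-breath gaps, Gaussian gap-to-gap transitions `N(k−j; μ = j−i, σ²)`,
   emissions `BB(i)·BB(j)`, decoded by Viterbi; the rate is 60 over the mean
   decoded inter-breath interval. An exhaustive enumeration oracle verifies
   the decoder exactly on small instances.

A synthetic-data module generates boundary-annotated breathing audio,
periodic video grid features, detector-like boundary-probability series, and
SNR-controlled noise mixtures, so the entire pipeline is testable without any
external corpus. An evaluation module provides MAE, Bland–Altman statistics,
AUROC, Welch method comparison, and noise-robustness sweeps.

## Worked example

```r
library(respirate)

# 60 s of synthetic breathing at 20 breaths/min, with annotations
g <- synth_breath_audio(duration_s = 60, true_rate = 20, seed = 42)
measure_snr(g$clip, g$annotations)   # 40.3 dB

X <- log_mel_spectrogram(g$clip)
X
#> <frame_features> audio: 80 channels x 1798 frames @ 29.963 frames/s
estimate_rr_autocorr(X, k = 30)
#> <rr_estimate> 20.66 breaths/min  [autocorr-audio]  l_max = 2.904 s

# video route: 84 grid channels, 8 of them periodic
v <- synth_video_features(duration_s = 60, true_rate = 20, seed = 42)
estimate_rr_autocorr(v$features, k = 30)
#> <rr_estimate> 19.93 breaths/min  [autocorr-video]  l_max = 3.010 s

# boundary-probability routes at a high rate (33 breaths/min)
s <- synth_boundary_probs(duration_s = 30, true_rate = 33, seed = 42)
rr_from_boundaries(s$p)
#> <rr_estimate> 32.10 breaths/min  [bb]  l_max = 1.869 s
estimate_rr_hsmm(s$p)
#> <rr_estimate> 31.28 breaths/min  [bb-hsmm]  l_max = 1.918 s
```

The printed rate is breaths per minute; `l_max` is the chosen breath interval
in seconds (for the HSMM, the mean decoded inter-breath interval). Estimates
differ from the nominal 20/33 by the realized interval jitter of the
generated clip plus the lag-grid resolution; the rate-recovery tests bound
these errors (MAE ≤ 1 breaths/min for video, ≤ 2 for audio across
12–30 breaths/min).

Training the boundary detector on synthetic clips:

```r
train <- synth_boundary_dataset(200, duration_s = 30, seed = 11)
model <- train_boundary_model(train$features, train$labels,
                              boundary_model_config(seed = 11))
p <- predict_boundaries(model, train$features[[1]])
rr_from_boundaries(p)
```

A thin command-line front end wraps the same functions
(`inst/cli/respirate.R`): subcommands `synth`, `mix`, `features`, `estimate`,
`train-bb`, `sweep`, each emitting JSON with the resolved configuration and
seed.

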