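---
title: "Attention-based PSO-LSTM emotion estimation: models, choices, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based PSO-LSTM emotion estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

`psolstm` classifies a subject's emotional state from short windows of
multichannel EEG. For DEAP-style recordings the classes are the four
valence–arousal quadrants (HVHA, LVHA, LVLA, HVLA) obtained by thresholding
the subject's continuous 1–9 ratings at 5 (strictly greater = "high"); for
SEED-style recordings they are negative/neutral/positive. One model is
trained per subject, and the headline accuracy is the mean over subjects.

The pipeline has three stages:

1. **Baseline-relative time-domain features.** Each trial is cut into
   non-overlapping 3-s windows (384 samples at 128 Hz; 600 at 200 Hz). The
   first window is the baseline — the pre-stimulus state for DEAP, the first
   3 s of the stimulus for SEED, which provides no pre-stimulus recording —
   and is subtracted sample-wise from every later window. The residual
   amplitude changes, z-scored per channel, are the features; each window
   becomes one training example of shape `timesteps x channels`, labelled
   with its trial's class. A 63-s DEAP trial therefore yields 20 examples,
   a 60-s SEED trial 19.

2. **A two-layer LSTM with additive attention.** Each example is fed with
   time as the recurrence axis. The network is LSTM(units1, sequence output)
   → BatchNorm → Dropout → LSTM(units2, sequence output) → BatchNorm →
   Dropout → attention → dense(tanh) → dense(softmax). The standard LSTM
   cell is used: sigmoid forget/input/output gates, a tanh candidate state
   with its own weights, `c_t = f∘c_{t-1} + i∘c̃_t`, `h_t = o∘tanh(c_t)`.
   The attention layer scores every (post-normalization) hidden state
   against the final one, `score_t = v_a' tanh(W_a [h_t; h_n])`, softmaxes
   the scores over time, and forms the context vector `c = Σ_t a_t h_t`.
   The classifier head sees `[c; h_n]`. Setting `attention = FALSE` removes
   the context path (the head sees `h_n` alone), which is the
   "without-attention" ablation.

3. **Particle swarm hyperparameter search.** Five quantities are tuned:
   `units1` (1–200), `units2` (1–200), `dense_units` (1–200), `dropout`
   (0.1–0.9) and `batch_size` (1–128). Particles move in the continuous
   box with the textbook updates
   `v' = w v + c1 r1 (p - x) + c2 r2 (g - x)` and `x' = x + v'`; integer
   dimensions are rounded only when a position is decoded for evaluation, so
   the update rules stay exact. A particle's fitness is the minimum
   validation cross-entropy reached when a model built from its decoded
   position is trained on the fixed train split. After the final iteration
   the winning configuration is retrained from scratch and evaluated once on
   the held-out test split; the winning particle's weights are not reused,
   so the test set sees exactly one model.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| window length | 3 s | the segmentation unit of the protocol |
| quadrant threshold | 5, strict `>` | midpoint of the 1–9 scale; a rating of exactly 5 must land somewhere deterministic, and the comparator is configurable |
| standardization | per subject per channel, population sd | mirrors the per-subject pipeline; a leakage-safe `train_stats_channel` scope is available |
| swarm | w = 0.2, c1 = 0.3, c2 = 0.5, 15 particles, 10 iterations | the protocol's swarm settings |
| training | 150 epochs, Adam lr 1e-4, categorical cross-entropy, 60/20/20 shuffled split | the protocol's training settings |
| fitness epochs | = epochs | full-length training per particle by default; configurable because a reduced setting is essential at desk scale |
| fixed ablation | units (128, 64), dense 16, dropout 0.2, batch 32 | the fixed-hyperparameter baseline configuration |

Choices the protocol leaves open, fixed here once:

* **Candidate-gate parameters.** The candidate state c̃ uses its own weight
  matrices and bias rather than sharing the forget gate's; sharing would
  contradict the standard cell that the surrounding description assumes.
* **v_a is a projection, not a bias.** The score is the inner product of
  `v_a` with the tanh-transformed projection; that is what the scoring
  formula states, and a scalar "bias" would make all scores equal up to a
  monotone map.
* **Attention attends over the second (top) LSTM layer's states**, i.e. the
  sequence that feeds the head, as is conventional in stacked recurrent
  classifiers. `attn_dim` defaults to `units2`.
* **Normalization order and axis.** BatchNorm normalizes each hidden unit
  over all (example, timestep) pairs of the minibatch, with running
  statistics frozen at evaluation; dropout follows normalization. Evaluation
  mode is therefore fully deterministic.
* **The head reads the post-normalization, post-dropout final state**, the
  same tensor the attention layer sees.
* **Bound handling.** Positions are clamped to the box; velocities are
  clipped to plus/minus one range per dimension. `r1`, `r2` are drawn per
  dimension (anisotropic exploration). Updates are synchronous: all
  particles are evaluated, then the global best moves once per iteration,
  which makes the best-loss trace non-increasing by construction and the
  whole log bit-reproducible from one seed.
* **Velocity initialization** is uniform in plus/minus 10% of each range.
* **Fitness caching.** Evaluations are memoized on the decoded
  (integer-rounded) configuration, so a swarm that revisits a configuration
  does not retrain it.

## Numerical engine

No deep-learning framework is used: the forward pass, backpropagation
through time (both LSTM layers, batch normalization, dropout, attention and
the dense head) and the Adam loop are implemented in RcppArmadillo, with the
input projections and weight-gradient accumulations batched over time into
single matrix products. Correctness is established two ways in the test
suite: analytic gradients of every parameter block agree with central finite
differences to ~1e-8, and the compiled layer reproduces a pure-R single-step
reference cell to 1e-10. All randomness (initialization, shuffling, dropout
masks, swarm draws) is drawn from R's RNG, so a single `set.seed()`
reproduces a run bit-for-bit. Numerical guards: probabilities are clamped at
1e-12 inside the loss, batch-norm variance carries an epsilon of 1e-5, and a
constant channel z-scores to zero rather than dividing by zero.

## The synthetic benchmark, and what it does (not) show

`synth_config()` / `generate_recording()` emulate the per-subject array
layouts (40 × 32 × 8064 at 128 Hz with four rating columns; 45 × 32 × 12000
at 200 Hz with labels in {-1, 0, 1}) with a known class-conditional signal.
Because the feature model defines emotion as amplitude change relative to
baseline, class effects are injected into the experimental windows only:
each class adds a constant offset on its own channel subset plus a
class-specific sinusoid inside the 4–45 Hz passband, both of amplitude
`snr × noise_sd` on top of white Gaussian noise. Ratings are placed in the
quadrant interiors (high ≈ 7–8, low ≈ 2–3) so the quadrant rule recovers the
intended class exactly. `effect_recovery_check()` confirms the extraction
stage estimates the injected offsets.

The generator is a statistical benchmark, not a physiological simulation:
it has no 1/f background, no spatial correlation between electrodes, no
artifacts and no non-stationarity. Passing its tests shows the pipeline
recovers class-conditional structure of the kind the feature model assumes;
it says nothing about accuracy on real EEG.

Unit tests and the acceptance script run a reduced "desk-scale" profile
(`desk_profile()`): 8 trials × 8 channels with full-length 8064-sample
trials (so the 21-window segmentation is untouched), unit bounds capped at
16, batch size capped at 32, a 5-particle × 3-iteration swarm, 10 fitness epochs, and a
30-epoch final fit at Adam learning rate 0.005 — the usual learning-rate
scale for nets this small; the full-scale defaults above are unchanged. The
swarm-precision benchmark (a 5-d sphere over the hyperparameter box) uses
the canonical convergent coefficients w = 0.5, c1 = 1, c2 = 2 with 30
particles and 200 iterations, because the protocol coefficients are tuned for
a 10-iteration noisy search, not for high-precision convergence.

## A caution about the segment-level split

The protocol shuffles 3-s segments before splitting 60/20/20, so segments
of the same trial appear in both training and test sets. Because every
segment of a trial shares the same subtracted baseline window, each trial
carries a persistent "fingerprint", and a classifier can score far above
chance by recognizing the trial rather than the emotion. The package
demonstrates this directly: with the class signal removed entirely
(`snr = 0`), the default segment-split pipeline still reaches near-perfect
test accuracy, while (i) shuffling the labels at segment level — which
destroys the trial-to-label association — drops accuracy to chance, and
(ii) the grouped per-trial split (`split_data_grouped()`, or
`run_subject(..., split_mode = "trial")`), which keeps whole trials out of
training, drops it to chance as well. At high SNR the grouped split still
scores highly, so the class signal itself does transfer across trials.
Users who want accuracy estimates that generalize to unseen trials should
prefer `split_mode = "trial"`; the segment-level default is kept because it
is the protocol being implemented, and subject-level accuracies under it
should be read with this caveat.

## Reading the DEAP and SEED dialects

`read_deap()` accepts the per-subject pickle or MATLAB container (entries
`data`, `labels`); peripheral channels 33–40, if present, are dropped, and
only valence/arousal are used for labelling. `read_seed()` reads session
files of 15 named trial matrices, selects 32 electrodes by name — the
62-name cap order is supplied by `seed_montage()` and the 32-channel subset
is a required user choice, since the matched subset is site-specific —
crops each clip to its centered 60 s, and stacks sessions (three sessions =
45 trials). Both parse the foreign binary formats by delegating to the
Python interpreter's `pickle`/`scipy.io` and transferring raw float64
arrays, so no binary parsing is re-implemented; round-trips are bit-exact.
The package's own canonical container (`write_canonical()`) is a versioned
single-file structure with bit-exact arrays. Tests fabricate both dialects
from code; no restricted data is required anywhere.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` use: the 8 × 8 desk profile for
end-to-end runs (160 examples of 384 × 8; five seeds for the recovery,
ablation and control claims), 16-trial recordings for the grouped-split
demonstrations, 24-trial recordings for the effect-recovery estimates
(whose standard errors are clustered by trial, since segments within a
trial share the subtracted baseline), full 40 × 32 × 8064 and
45 × 32 × 12000 recordings for the
structural counts (800 and 855 examples), and tiny toys (2–7 timesteps,
1–5 units) for every equation-level oracle.

## Known limitations

* Subject-dependent only; no cross-subject transfer or pooling.
* Time-domain amplitude features only — no spectral or connectivity
  features.
* The swarm runs a fixed iteration budget; no adaptive stopping.
* Accuracies under the default segment split overstate generalization to
  unseen trials (see the caution above).
* Training is single-threaded and desk-scale profiles are sized for small
  models; full 150-epoch, 200-unit searches are computationally heavy.
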