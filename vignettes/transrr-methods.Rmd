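---
title: "TransRR: model, pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TransRR: model, pipeline, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Respiratory rate (RR, breaths per minute) is a first-line vital sign, yet it
is still mostly counted by hand. Respiration leaves three measurable imprints
on cardiac signals: **baseline wander** (BW, an additive low-frequency
component), **amplitude modulation** (AM, breathing modulates pulse
amplitude), and **frequency modulation** (FM, respiratory sinus arrhythmia
modulates the beat-to-beat rate). `transrr` estimates RR from simultaneous
16 s windows of ECG and PPG by (i) isolating the respiratory band from both
channels and (ii) regressing RR from the two cleaned waveforms with TransRR,
a Transformer-encoder network augmented with inception-style convolution
blocks.

## Preprocessing pipeline

`preprocess_dataset()` applies, in order, with all knobs in
`preprocess_params()`:

1. **Subject exclusion.** Subjects aged 5 years or younger
   (`max_age_excluded = 5`; young children breathe much faster and distort
   the label distribution) and subjects with more than 75% of the reference
   RR missing (`max_missing_rr_fraction = 0.75`) are dropped.
2. **Resampling.** Signals to `fs_target = 125` Hz, reference RR to
   `fs_rr_target = 1` Hz. The signal path uses polyphase rational resampling
   (the 300 to 125 Hz case reduces to 5/12), which preserves tone frequency
   and at least 95% of tone amplitude; an interpolating resampler would
   accumulate drift over 8-minute records. The RR trace, being slow, is
   linearly interpolated, and a resampled point inherits "missing" from its
   nearest source sample.
3. **Respiratory band-pass.** A 4th-order Butterworth over 0.1–0.6 Hz
   (6–36 breaths/min, the physiologically viable band), applied
   forward–backward so the filter is zero-phase and the waveform stays
   aligned with its labels. At 125 Hz these cutoffs sit at 0.2–1% of
   Nyquist, where the polynomial transfer-function form of the filter is
   numerically unusable; the design is therefore kept in pole form and
   realised as cascaded biquads (second-order sections), each initialised at
   its steady state so constant inputs map exactly to zero. The
   implementation agrees with an independent SOS design to ~1e-11 in
   magnitude response.
4. **VMD denoising.** Variational mode decomposition splits each channel
   into `vmd_modes = 5` narrow-band modes (bandwidth penalty
   `vmd_alpha = 2000`, dual step `vmd_tau = 0`, tolerance `1e-7`, centers
   initialised uniformly, mirror extension by half the signal on each side).
   The highest-center-frequency mode, which collects residual high-frequency
   motion artifact, is discarded and the rest are summed. "Last mode" is
   interpreted as highest center frequency after ascending ordering; the
   ADMM runs on the full-length trace, once per channel, not per window.
5. **Per-subject z-scoring.** Each channel is standardised to mean 0 and
   population SD 1 per subject, removing inter-subject amplitude variance
   (the dominant nuisance across subjects and datasets). Population rather
   than sample SD is used everywhere in the package for internal
   consistency; the difference is O(1/n). The `zscore = FALSE` switch exists
   only for the ablation experiment.
6. **Windowing.** 16 s windows with 87.5% overlap (2 s stride); the window
   count is `floor((duration - 16)/2) + 1`. The label is the arithmetic mean
   of the 1 Hz reference-RR samples whose timestamps fall in
   `[start, start + 16)` (a median option exists); windows touching a
   missing RR sample are dropped. The mean is the simplest unbiased summary
   of a slowly varying rate over a short window.
7. **Label-range filter.** Segments with labels at or outside (5, 30)
   breaths/min are removed — only the strict interior is kept.
8. **Decimation.** Windows are decimated by plain stride 8 to length 250.
   No extra anti-aliasing is needed: the signal is already confined below
   0.6 Hz, far under the post-decimation Nyquist of ~7.8 Hz. Decimating at
   segmentation time (rather than inside the model's input layer) makes
   stored segments model-ready; the two placements are mathematically
   identical.

The pipeline contains no randomness: identical inputs and parameters give
identical segment sets, summarised by a parameter fingerprint that archives
and checkpoints carry along.

## The TransRR model

The input module adds a sinusoidal positional encoding
(`PE[pos, 2i] = sin(pos/10000^(2i/d))`, cosine in odd columns; with d = 2
the sine column goes to the ECG channel and the cosine column to the PPG
channel) and stacks both channels into a 250 x 2 matrix. Four Transformer
modules follow (`model_config()`); each maps an L x W activation to L x W:

- **Multi-head self-attention** with 8 heads of head size 32 (inner width
  256), projected back to W; residual add of the block input; layer
  normalization.
- **Kernel inception**: parallel same-padded 1-D convolutions with kernels
  3, 5, 7, 9 (8 channels per branch, ReLU), concatenated; dropout (0.2).
- **Dilation inception**: parallel kernel-5 convolutions at dilation rates
  1, 4, 8, 16 (8 channels per branch, ReLU), concatenated; a pointwise
  convolution restores W channels.
- A second residual connection, taken from the output of the first layer
  normalization (the standard encoder topology), and a second layer
  normalization.

The head flattens L x W and applies fully connected layers of sizes 256,
64, 16, 1 (ReLU hidden activations, dropout after each hidden layer, linear
output = predicted RR).

Design points the architecture description leaves open, and the choices
made here (all configurable):

- **Module width W.** The residual connections force the working channel
  count to equal the block input's; the literal reading of the
  concatenated two-channel input gives W = 2, which is the default. A
  learned pointwise input projection activates automatically if W is set
  differently.
- **Layer normalization axis.** With W = 2 channels, normalising each time
  step across its two channel values is degenerate (it collapses every
  position to a sign pattern and amplifies noise where the channels agree),
  so normalization is computed over the whole L x W activation per example,
  with a per-channel affine — the same spirit as the per-subject z-score,
  and strictly per-example (predictions are batch-independent).
- **Branch width** (8 per inception branch), **dropout** (0.2 wherever
  dropout appears), **activations** (ReLU in convolutions and hidden FC
  layers, linear output): conventional defaults, stated rather than
  inferred.
- **Attention projections** map W to 8 x 32 and back with learned linear
  maps — the only shape-consistent way to honour both the stated head
  geometry and the residual.

### Numerical implementation

The forward and backward passes are hand-derived and compiled
(RcppArmadillo). Since scores depend on the input only through an
(W+1) x (W+1) bilinear form per head, attention is evaluated in a low-rank
form that never builds L x head-size intermediates inside the L x L
products. The L x L softmax kernels run in single precision with a
polynomial `exp` (relative error ~1e-5, far below the optimizer's noise
floor); everything else — parameters, gradients, Adam state, layer
normalization, convolutions, the FC head — is double precision. Gradient
correctness is enforced by finite-difference tests (directional and
coordinate-wise). Training, initialization (Glorot-uniform, seeded), batch
shuffling and dropout use a self-contained deterministic generator, so a
single master seed reproduces a run bit-for-bit on the same platform.

## Training protocol

`train_config()` defaults: MAE loss, Adam (beta 0.9/0.999, eps 1e-8), up to
100 epochs at batch size 128, learning rate 1e-3 multiplied by 0.9 whenever
the validation loss fails to improve for 5 consecutive epochs (floored at
1e-4), early stopping after 20 epochs without improvement. "No decrease in
loss" is read as *validation* loss — watching training loss would defeat
early stopping — and the returned parameters are those of the best
validation epoch, the natural partner of validation-based stopping.

Splits are always at subject level: `subject_kfold()` deals shuffled
subjects into folds differing by at most one; within the training folds,
20% of subjects (at least one) form the validation set. Any construction
that puts one subject's segments on both sides of a split is a hard error
(`transrr_leakage_error`), never a warning — segment-level splits leak
because neighbouring overlapping windows are nearly identical.

## Metrics

`evaluate()` reports MAE (breaths/min), E = MAE / |mean reference RR| (a
fraction; the conventional x100 display is available via `as_percent`),
Pearson correlation (population convention in numerator and denominator,
hence identical to the sample convention), and 95% Bland–Altman limits of
agreement `mean(d) ± 1.96 sd(d)` on d = predicted − reference.
Cross-validation aggregates by the unweighted mean of each metric across
folds (for the limits of agreement, the mean of the per-fold bounds). Each
fold's report also carries the MAE of the predict-the-training-mean
baseline, the floor any useful regressor must beat.

## The synthetic cohort

`generate_subject()` synthesises a quasi-periodic cardiac carrier (a
Gaussian-peak train for ECG, a raised cosine for PPG — after the 0.1–0.6 Hz
band-pass only the dominant first harmonic matters, so pulse morphology is
irrelevant) whose baseline, amplitude, and instantaneous rate are modulated
by a known respiratory phase. The RR trace driving that phase is a
reflected Gaussian random walk at 1 Hz (default drift 1 breath/min per
minute) between 8 and 28 breaths/min; mean heart rate is uniform on 55–95
beats/min. White noise (SD 0.1 of the carrier) and one sinusoidal 20 Hz
motion-artifact component (amplitude 0.2) are added per channel. `rr_ref`
is exactly the trace used for modulation, so any label error measured
downstream is attributable to the pipeline, not the fixture.

What the generator does *not* emulate: realistic ECG/PPG morphology
(P/QRS/T fiducials, pulse-wave shape), broadband or transient motion
artifacts, sensor dropouts, pathology-dependent modulation depths, or the
age structure of clinical cohorts. Passing the recovery experiments below
therefore demonstrates that the pipeline and model are implemented
coherently and can extract a respiratory frequency they are designed for —
not that clinical accuracy figures transfer.

## Desk-scale study conditions

The full protocol (95 subjects of 8 min, ten-fold cross-validation, 100
epochs) is a multi-hour GPU-era computation on data that must be downloaded
separately. The package's own experiments run the identical code path at
desk scale, with sizes chosen once as the package's reference conditions:

- **Recovery experiment**: 16 synthetic subjects of 120 s at the generator
  defaults (master seed 7), subject-level 5-fold cross-validation, a
  2-block model, 30 epochs at batch size 32, training on every second
  window per subject (the 87.5% overlap makes neighbouring windows
  near-duplicates; validation and test always use every window). Quality
  gates: mean test MAE at most 2.0 breaths/min, mean PCC at least 0.7, and
  at least a 30% improvement over the training-mean baseline. Subject
  count matters more than segment count here: every subject is tested in
  exactly one fold, so test subjects whose mean RR falls outside the
  training subjects' coverage measure extrapolation, and with very few
  subjects those gaps dominate the fold means.
- **Ablations**: removing z-scoring, the kernel-inception block, or the
  dilation-inception block is re-run on the first fold of the same
  partition and must not improve on the full model's MAE there (a
  directional check; with one fold and twelve subjects, magnitudes are not
  comparable to the full-scale ablation table).
- **Capacity check**: the default 4-block model must drive its training MAE
  on 32 segments below 0.5 breaths/min within 300 epochs.

Thresholds were fixed from the structure of the task (the baseline MAE of a
uniform 8–28 cohort is ≈ 5 breaths/min; 2.0 requires genuine frequency
reading), not tuned to observed runs.

## Known limitations

- With W = 2 the attention blocks have little representational width; most
  capacity sits in the FC head. This is the faithful reading of the
  architecture description, not a capacity-optimised variant.
- VMD's "discard the last mode" rule only removes artifacts that actually
  concentrate in the highest-frequency mode; on spectrally sparse inputs
  (e.g. a pure two-tone test signal) adjacent modes can absorb an artifact
  and the rule removes almost nothing. After the band-pass this is rarely
  consequential, and it mirrors the reference procedure.
- Reference RR derived from breath annotations is held piecewise-constant
  between onsets (with edge hold). If the original labels were produced
  with a different interpolation, small systematic label differences result.
- The package reads one reference RR trace per subject; where two
  independent annotation sets exist, they should be merged (e.g. averaged)
  upstream by the conversion script.
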