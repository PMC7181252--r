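---
title: "Detecting freezing of gait from a waist-worn accelerometer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting freezing of gait from a waist-worn accelerometer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Freezing of gait (FOG) is a transient inability to continue walking that
affects many people with advanced Parkinson's disease. Because episodes are
brief, unpredictable and strongly context-dependent, clinically useful
detectors must run on unobtrusive hardware — here a single waist-worn triaxial
accelerometer — and must work with low latency so they can drive rhythmic
cueing that helps the patient resume walking.

The physiological signature fogkit exploits is spectral: normal gait
concentrates acceleration power in the *locomotion band* (0.5–3 Hz), while
FOG episodes show leg trembling with a dominant frequency of 6–8 Hz inside
the wider *freeze band* (3–8 Hz). The *freeze index* — freeze-band power
divided by locomotion-band power — rises sharply during FOG.

## Pipeline

1. **Preprocessing** (`resample_to`, `bandlimit`, `window_and_label`). Raw
   200 Hz signals are decimated to 40 Hz with an anti-aliased polyphase FIR
   resampler (40 Hz fully covers the sub-20 Hz band of interest), then
   filtered per axis with a causal second-order Butterworth low-pass at 15 Hz
   followed by a causal third-order high-pass at 0.2 Hz (gravity removal).
   Filtering is single-pass because the motivating application is low-latency
   cueing; zero-phase filtering would be acausal. Windows are 128 samples
   (3.2 s) with 0/50/75% overlap; a window is labeled FOG only when more than
   50% of its samples are annotated FOG, non-FOG only when none are, and
   mixed windows are discarded (the discard tally is kept so the class ratio
   can be audited).
2. **Representations** (`featurize`). Three per-window representations:
   21 hand-crafted statistics (per axis: mean, SD, variance, spectral
   entropy, energy, freeze index, total 0.5–8 Hz band power); 36 inertial
   MFCCs (20 triangular mel filters remapped onto 0–20 Hz, log energies
   floored at 1e-10, orthonormal DCT-II, coefficients c0–c11); and the
   symmetric 64-bin half of a 128-point FFT per axis (192 values). The
   spectral representation can be stacked with up to three *previous* windows
   of the same recording (contextual windows, 384/576/768 values), never
   crossing recording or subject boundaries.
3. **Detectors** (`build_autoencoder`, `build_cnn`, `build_cnn_lstm`,
   `fit_shallow`). Two novelty detectors trained on normal movement only
   (linear one-class SVM; a denoising autoencoder 192–80–40–20–40–80–192
   scored by reconstruction RMSE) and five supervised classifiers (RBF SVM
   with gamma 0.3 and cost 1; AdaBoost with 100 stumps; random forest with
   100 trees; a 1-D CNN with two conv/pool blocks of 32 filters and kernel 8;
   and a time-distributed CNN-LSTM that applies a shared conv stack of
   128-then-64 filters with kernel 4 to each stacked window before a 64-cell
   LSTM and dense 80/40/1 head). Deep models train with binary cross-entropy,
   Adam (RMSprop for the autoencoder), learning rate 1e-4, element-wise
   gradient clipping at 1, early stopping after 20 stagnant epochs, and
   default batches of 512 (1024 for the CNN-LSTM). Every detector stores its
   training-fold maximum for 0–1 scaling and returns scores oriented so
   higher = more FOG-like.
4. **Evaluation** (`loso_evaluate`, `r10fold_evaluate`, `roc_metrics`).
   Leave-one-subject-out (generic model) and within-subject random 10-fold
   (personalized model). Sensitivity and specificity are read at the
   equal-error operating point (the threshold minimizing |sensitivity −
   specificity|, ties toward the lower threshold), together with their
   geometric mean, trapezoidal AUC, and EER. Aggregates are arithmetic means
   over folds (and repeats, which differ only in seeds — the data stay
   fixed). R10fold with overlapped windows leaks raw samples between train
   and test; the report quantifies that sharing instead of hiding it, and a
   `grouped` option documents the contiguous-block fix without making it the
   default protocol.

## The synthetic cohort

No clinical recordings ship with the package, so a simulator
(`simulate_cohort`) generates labeled cohorts with the statistical structure
the method assumes:

* a semi-Markov state machine alternates walking bouts (mean 25 s) and
  standing pauses (probability 0.35, mean 8 s);
* walking is a per-subject gait fundamental (1.4–2.2 Hz) with harmonics kept
  inside 0.5–3 Hz, amplitude 0.25–0.45 g, on three axes via fixed gains, with
  1 g gravity on the vertical axis and white sensor noise (0.03–0.08 g);
* FOG episodes (tremble frequency 6–8 Hz) are carved out of walking bouts and
  carry the temporal phases described for real freezes: a 1.2–2.2 s
  pre-freeze transition in which gait amplitude collapses and trembling ramps
  up (still labeled non-FOG), a strong onset, and a decay to 35–65% of onset
  amplitude by the episode's end;
* brief broadband movement artifacts (2–4 per minute, 0.4–1.5 s, multi-tone
  2–11 Hz at roughly gait amplitude) emulate unscripted daily activities;
  they are labeled non-FOG although their power reaches into the freeze band.

The last two points matter. Without them a FOG episode is a stationary pure
tone, which every detector — including a one-class SVM — separates almost
perfectly, so the phenomena of interest (context helps; supervised beats
novelty detection) would be invisible. With them, mid-episode windows are
genuinely ambiguous in isolation while the preceding windows carry the
onset signature, which is exactly the structure the contextual CNN-LSTM is
designed to exploit; and isolated artifact windows produce false alarms for
detectors that cannot consult context or labels.

Episode rate defaults derive from the target class balance: with mean
episode duration drawn in 4.5–8 s, the per-subject rate is set to
`target_fraction * 60 / duration` (±15% jitter), so the default 21-subject,
two-session cohort realizes about 10.5% FOG samples (a ~10:1 imbalance).
The `fog_contrast` argument scales trembling amplitude relative to gait and
acts as a difficulty knob.

What the simulator does **not** emulate: biomechanically realistic gait
waveforms, medication ON/OFF states, sensor drift or saturation, postural
transitions, or inter-axis phase structure. Passing tests on this cohort
therefore demonstrate that the pipeline's machinery is correct and that its
comparative behavior matches the expected qualitative pattern — not that the
reported clinical accuracies transfer to patients.

## Numerical and scaling choices

* The network engine stores conv-domain activations channel-blocked with the
  batch index fastest; convolutions run in single precision through BLAS
  (the two conv/pool blocks are fused in compiled code), while dense and
  LSTM layers stay double precision. Max-pool ties break toward the earlier
  sample; dropout is active only during training; all training randomness
  (initialization, shuffling, dropout, denoising noise) derives from the
  configuration seed, so identical seeds reproduce scores to float
  precision.
* The resampler is a Kaiser-windowed (beta 5) polyphase FIR with 10 taps per
  phase, mirror-padded edges and delay compensation; labels map by nearest
  neighbor. Filter edge transients at recording starts are kept, not
  trimmed.
* Degenerate windows: an all-zero window has spectral entropy 0 and freeze
  index 0 by convention (locomotion power below 1e-12 would otherwise make
  standing windows explode the ratio).
* Test problem sizes: the packaged experiments run on cohorts of 2–6
  subjects and 2–10 minutes per recording. The contextual-window trend
  experiment uses a 6-subject, 10-minute cohort at `fog_contrast = 0.6`
  (chosen so AUCs sit in the discriminative 0.85–0.95 range rather than at
  ceiling), with 6 training epochs at batch 256. The full-scale default batch of
  1024 would yield only 3 optimizer updates per epoch on ~3,500 training
  windows, so at this scale the batch is reduced to keep the number of
  updates commensurate with the full-size protocol; training-loss curves
  confirm the short runs are past the initial plateau.

## Known limitations

* The AdaBoost baseline is a hand-written discrete AdaBoost on depth-1
  trees; ensemble internals (tie handling, early termination at zero error)
  follow the textbook algorithm rather than any specific library.
* EER is computed per fold on that fold's pooled scores; the cohort EER is
  the mean of fold EERs. Whether aggregate AUC should instead pool scores
  across folds is a protocol ambiguity; mean-of-folds was chosen to match
  per-patient reporting.
* The CNN-LSTM's single-precision convolutions bound reproducibility across
  BLAS builds at ~1e-6 relative, which is why the reproducibility contract
  in the tests is stated at that tolerance.
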