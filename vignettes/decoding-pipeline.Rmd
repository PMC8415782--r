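---
title: "Decoding sustained movement and touch from intracranial band-power features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sustained movement and touch from intracranial band-power features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stereo-EEG (SEEG) depth electrodes and electrocorticography (ECoG) grids
record field potentials during cued tasks — sustained finger flexions, hand
open/close, tactile taps on finger pads. Two empirical facts shape the
decoding problem this package addresses. First, evoked band-power
modulations are mostly *phasic*: transient bursts after the cue onset (and
often after the offset), much shorter than the sustained movement they
accompany; a smaller set is *phasic-tonic* and holds through the cue.
Second, modulation amplitude varies substantially trial to trial, so a
feature that looks informative on one trial may contribute mostly noise on
average. The pipeline therefore (i) reduces raw voltages to standardized
band-amplitude features, (ii) selects features by the *repeatability* of
their temporal response across trials, and (iii) compares a memoryless
per-window classifier (gaussian-kernel SVM) against a sequence model (LSTM)
that can convert transient inputs into sustained predictions.

## Feature extraction

1. **Bipolar derivation.** Adjacent contacts on each lead are subtracted
   (contact *i* minus contact *i + 1*), suppressing common-mode noise. Gaps
   in the contact numbering are never bridged, and grid rows are treated
   like lead chains.
2. **Windowed spectra.** Non-overlapping 200 ms Blackman-tapered windows,
   anchored at the recording start, each followed by a short FFT. The bin
   spacing is `1 / 0.2 s = 5 Hz` at any sampling rate.
3. **Band integration.** One-sided amplitudes are *summed* over six bands:
   0–10 (delta/theta), 10–15 (alpha/mu), 15–30 (beta), 30–100 (gamma 1),
   100–500 (gamma 2) and 500–5000 Hz (gamma 3). Intervals are half-open
   `[low, high)` so the shared edges are counted exactly once; with
   summation, bands that partition the spectrum conserve total amplitude.
   The DC bin belongs to the lowest band, so slow evoked-potential energy
   is deliberately part of the 0–10 Hz feature. Bands entirely above
   Nyquist are dropped; a band straddling Nyquist is truncated (both with
   warnings), so the same code handles reduced-rate acquisitions.
4. **Boxcar smoothing.** A centered 1 s (5-window) moving average with
   shrinking-window edges. Centered smoothing preserves response latency,
   which matters because feature selection correlates temporal shapes; a
   `causal_boxcar` option provides trailing-window smoothing for real-time
   parity.
5. **Standardization.** Each feature is z-scored across the entire task.
   Zero-variance features are excluded with a warning, never silently
   zeroed, and the constants are stored for inverse transforms. Whether
   standardization should instead be fit on training windows only is an
   evaluation-design question (the all-task variant mildly leaks test
   statistics); both are supported (`standardize`, plus selection and
   training always restricted to training trials downstream).

The operation order is taper → FFT → band-integrate → boxcar → standardize.

## Repeatability selection (MCC)

Features are epoched from each cue onset (snapped back to the window grid)
to 400 ms after the cue offset — a 4 s cue spans 0–4.4 s, 22 windows. The
per-class trial average is the *composite temporal response*; the **mean
correlation coefficient (MCC)** of a feature is the average Pearson
correlation between each trial's trace and the composite. By default each
trial participates in its own composite (`include_all`, the literal
definition), which is optimistically biased at small trial counts; a
`leave_one_out` mode removes that bias and is verified in the tests to be
less optimistic on pure noise. Degenerate traces (zero-variance trials or
composites) are excluded from the average and flagged.

Two selection rules are implemented because the source methods are
ambiguous: a strict threshold (`">0.6"`, the rule the results and figure
annotations actually apply) and a closed range (`"0.4:0.6"`, the rule the
methods text states). The default is `">0.6"`. Selection is computed per
class and unioned, and — in the decoding workflow — always from training
trials only.

## Decoders

Both decoders classify every 200 ms window into rest (class 0) or one of
the cue classes; rest is an explicit class because realistic use requires
predicting through rest periods. The headline metric is window-wise
accuracy (the accuracy denominator is otherwise ambiguous; trial-wise
majority voting can be derived from the exported prediction traces). The
chance level reported alongside is the frequency of the majority test
label. `mean ± SD` is computed over `n_repeats` re-trainings with different
seeds on the same contiguous split; the train/test split is contiguous in
time at a trial boundary, so no window of any trial appears in both
partitions.

**SVM.** `e1071::svm`, RBF kernel, one-vs-one multiclass, per-window IAF
vectors with no temporal stacking — deliberately memoryless, because its
contrast with the LSTM is the scientific point. `gamma` and `cost` are
tuned by a small grid with blocked (contiguous) cross-validation folds on
the training windows.

**LSTM.** A single-layer LSTM with a per-window softmax head, written in
plain R matrix algebra and trained by backpropagation through time with
Adam (gradients are verified against a finite-difference oracle in the
test suite). Defaults: 32 hidden units, learning rate 0.02, 200 epochs,
L2 weight decay 1e-3, gradient-norm clip 5, forget-gate bias 1, three
restarts. Three design choices matter in practice and were validated on
synthetic data:

* *Trial-aligned chunks.* Training sequences are non-overlapping chunks of
  one cue + rest block, aligned so chunk boundaries fall on cue onsets.
  Misaligned or overlapping chunks present cue-labeled windows with no
  preceding onset evidence and measurably destabilize training.
* *Restarts instead of a validation split.* Per-window cross-entropy has a
  strong local optimum that predicts rest through entire cues. With the
  short sessions this package targets, a held-out validation split of one
  or two trials is dominated by single-trial amplitude variability and
  systematically prefers that degenerate optimum, so the default monitors
  training loss, controls capacity with L2, and keeps the best of three
  independent initializations. A validation fraction remains available for
  longer sessions.
* *State reset at prediction.* Test streams are predicted in `chunk_len`
  segments with a state reset between them, matching the sequence-length
  distribution seen in training; running arbitrarily long stateful streams
  through a model trained on short chunks degrades noticeably.

`architecture_grid()` runs the 2 × 2 design — {SVM, LSTM} × {all features,
MCC-selected} — on one split with shared seeds.

## The synthetic generator

No public recordings accompany the methods this package implements, so
`simulate_recording()` provides ground-truthed surrogates:

* **Task structure.** Cue blocks (default 4 s) alternating with rest
  (default 4 s), classes in randomized order, with a lead-in rest block.
  Durations must be multiples of 0.2 s so blocks align to the window grid.
* **Background.** Independent 1/f noise per contact (power exponent 2 by
  default, amplitude 10 µV) plus a small broadband component. The default
  sampling rate is 2 kHz — desk-scale, and faithful to reduced-rate
  acquisition; bands above Nyquist are clipped automatically.
* **Responses.** A configurable fraction of bipolar pairs carries planted
  modulations: band-passed Gaussian-noise carriers (so integrated band
  amplitude, not a line spectrum, is modulated) shaped by phasic,
  phasic + offset, phasic-tonic, or suppression envelopes, with per-trial
  amplitude jitter (CV 0.2 default) and onset-latency jitter (50 ms SD).
  Excitatory kinds default to gamma bands; suppressions are modeled as a
  tonic beta-band rhythm whose amplitude drops during the cue (classic
  movement-related desynchronization).
* **Planting that survives the montage.** Each carrier is added as a
  common-mode signal to the contiguous run of contacts from the lead tip
  through the target pair's first contact — a spatially extended source
  with an amplitude step between the pair's contacts. Chain subtraction
  cancels it everywhere except the target pair, so the ground-truth
  feature list is exact.
* **Calibration.** `effect_size` is the peak change of the integrated band
  amplitude in SD units of the pair's background band amplitude across
  windows. Because amplitudes of independent signals add in quadrature,
  the carrier scale solves `sqrt(mu^2 + rho^2) = mu + effect_size * sd`
  with `mu`, `sd` estimated from the generated background itself.
* **Spectral hygiene.** Carrier band edges are inset by one 5 Hz bin
  (where the band is at least two bins wide) so filter roll-off does not
  plant repeatable energy in adjacent integration bands. This is also why
  the default suppression band is beta rather than alpha/mu: at 5 Hz
  resolution the 10–15 Hz band is a single bin, and any band-limited tonic
  carrier there unavoidably contaminates the neighboring beta bin.

What the generator does **not** emulate: volume conduction and realistic
spatial correlation between leads, line noise and movement artifacts,
non-stationary background drift, cross-frequency coupling, and the
re-referencing subtleties of real grids. Passing tests on these surrogates
therefore demonstrates that the pipeline recovers what it is designed to
recover under its own model assumptions — not clinical-grade performance
on patient data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at 500 Hz with
1–2 leads of 8–16 contacts, 10–20 trials per class, 2 + rest classes —
sizes chosen so a full run stays comfortably on a single CPU while leaving
every stage statistically testable. Key numerical conventions: epoch
starts snap to the latest grid start at or before the cue onset; the
selection threshold is strict (`mcc > t`); trailing partial windows and
chunks are dropped; EDF encoding is 16-bit with per-channel symmetric
physical ranges (round-trip error bounded by one quantization step);
IAF persistence uses TSV + JSON (no binary sidecars).

## Known limitations

* `include_all` MCC inflates repeatability for very small trial counts;
  use `leave_one_out` when comparing across different numbers of trials.
* The LSTM is intentionally small and full-batch; it targets hundreds to
  thousands of windows, not hour-long sessions.
* Feature selection assumes equal cue durations within a class (or
  explicit cropping) so epochs share one grid.
* No permutation-based significance test for MCC is included; thresholds
  are fixed, as in the underlying method.
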