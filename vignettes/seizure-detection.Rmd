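---
title: "Self-supervised seizure detection: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised seizure detection: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegwatch)
```

## The detection problem

Continuous stereo-EEG (SEEG) monitoring in an epilepsy monitoring unit
produces hours of multichannel signal per patient, reviewed around the clock
by specialists. `seegwatch` frames seizure detection as *label-free anomaly
detection*: a forecaster is trained on the opening minutes of a patient's own
recording (no annotations required), and the points where the signal stops
being predictable — the forecast residuals — are classified by a
nonparametric threshold. A concurrent bedside video stream is reduced to a
per-frame *regularity score* by a convolutional-recurrent autoencoder and fed
through the identical residual-thresholding path, so both modalities emit the
same interval schema and can be pooled.

The pipeline for one channel is:

1. zero-phase 50 Hz low-pass FIR filtering and scaling to $(-1, 1)$;
2. a chronological train/test split (train fraction 0.20–0.50, default 0.30);
3. a forecaster fitted on the training segment only — a compact LSTM
   (80 hidden units, MSE loss, Adam, dropout 0.3, early stopping) or a
   deterministic Yule–Walker AR baseline that satisfies the same contract;
4. rolling one-step forecasts on the test segment; absolute errors smoothed
   with an exponentially weighted moving average, $e_s$;
5. per sliding window, the threshold $\varepsilon = \mu + z\sigma$ whose
   exceedances, when removed, maximally reduce the window's mean and
   standard deviation of $e_s$ (searched over a z grid), followed by
   *pruning*: flagged runs whose peak errors are not separated from the rest
   of the window by a relative drop of more than $p = 0.10$ are reclassified
   as normal;
6. event-level scoring of the merged intervals against labelled events
   (any-overlap rule): PPV, sensitivity, F1, plus forecast MAPE.

A conventional static baseline — one global threshold at
$\text{mean}(e_s) + 2\,\text{sd}(e_s)$ — is implemented for comparison,
because its failure mode (false positives on drifting, artifact-laden
records) is the motivation for the dynamic method. No parametric form is
assumed for the residuals anywhere; the threshold search and the pruning rule
operate on order statistics of the observed errors only.

## Conventions pinned throughout

* intervals are half-open $[\text{start}, \text{end})$ in 0-based sample (or
  frame) indices; seconds are obtained through the sampling rate;
* standard deviations in the threshold machinery are population
  (divide-by-$n$) deviations;
* exceedance is strict ($e_s > \varepsilon$); the retained set is its
  complement;
* objective ties across the z grid break toward the **larger** z (the more
  conservative threshold);
* the EWMA uses $\alpha = 2/(\text{span}+1)$ and is anchored at the first
  error value; `span = 1` disables smoothing exactly;
* MAPE excludes samples with $|x| <$ `denom_floor` (default $10^{-3}$):
  signals scaled to $(-1,1)$ cross zero, and percentage error at a
  zero-crossing is not informative;
* a detector that makes *no* predictions has undefined PPV, reported as `NA`
  with an explicit flag — never as 0 or 100;
* scaling parameters are fitted on the training segment only and reapplied
  to the test segment, so no test statistics leak into preprocessing.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `cutoff_hz` | 50 | Hz | clinical low-pass; kernel is windowed-sinc (Hamming), transition band 12.5 Hz, group delay compensated exactly |
| `train_fraction` | 0.30 | – | inside the 0.20–0.50 regime the training protocol prescribes |
| `hidden_units` | 80 | – | "80 hidden" is read as 80 units in one recurrent layer; 80 stacked layers is implausible for minutes-scale CPU training |
| `max_epochs`, `early_stop_min_delta`, `early_stop_patience` | 35, 0.003, 5 | – | the monitored-training regimen this pipeline emulates; improvement is measured against the best validation MSE so far, and the best-epoch weights are restored at stop |
| `history_window` $l_b$ | 250 | samples | forecast context; the forecaster emits one-step predictions aligned to `test[l_b:]` |
| `smoothing_span` | 1% of error length | samples | the source method's convention; exposed because the right scale is data-dependent |
| `window_size` | 300 s of samples | samples | see below — a time scale, not a point count |
| `z_grid` | 2.0–10.0 by 0.5 | – | threshold never sits below 2 local SDs |
| `penalized` | `FALSE` | – | see below |
| `prune_p` | 0.10 | – | the standard pruning fraction for this method family |
| `static_k` | 2 | – | the conventional mean ± 2 SD baseline |

### Why the window is a time scale

The source of the dynamic-threshold idea processes telemetry at one sample
per minute with windows of ~2000 points, i.e. windows spanning tens of
anomaly durations. Copying the *point count* to SEEG sampled at 256 Hz gives
an 8 s window — shorter than a seizure — and the objective then faces
bimodal windows in which $\mu + 2\sigma$ either exceeds every value (nothing
is flagged) or lands inside the event plateau (only the jittering top of the
event is flagged, and such shaved tops are exactly what pruning removes).
`detect_anomalies()` therefore sizes the window as 300 s of samples (capped
at the error-series length), restoring the window : anomaly ratio the method
was designed for. `dynamic_config()` still accepts any explicit size.

### Why the objective is unpenalized by default

Both objective forms are implemented. The penalized form divides by
(number of excluded points + number of excluded runs²). For anomalies a few
points long that penalty is mild, but an ictal event spans thousands of
samples at SEEG rates, so the penalty makes "shave the top of the event"
(a handful of points) beat "exclude the event" (thousands of points) at
every window — and shaved tops are then pruned, collapsing sensitivity.
The unpenalized form picks the separating threshold. The penalized variant
remains one flag away for short-anomaly regimes.

### Where pruning runs

The pruning prose in the source material is ambiguous between a global pass
and a per-window pass. Applied once globally over a long recording with many
flagged runs, the sorted-maxima rule almost never prunes (some late gap in
the descending-peak continuum exceeds $p$, keeping everything above it).
Pruning is therefore applied *within each sliding window*, on that window's
runs against that window's remaining errors, before the cross-window union —
which is also how the cited method's evaluation batches work. The standalone
`prune_anomalies()` keeps the global semantics for post-hoc use and is
tested against an independent hand-stepped oracle.

## The video path

Frames (grayscale, $[0,1]$) pass through an autoencoder with fixed layer
counts — 2 strided convolutions, 3 convolutional-LSTM layers,
2 transposed convolutions — implemented from scratch with im2col
convolutions and hand-written backpropagation through time (no deep-learning
package exists in the target environment); all gradients are verified
against central finite differences in the test suite. Per-frame
reconstruction errors $e(t)$ (sum of per-pixel squared errors by default;
absolute optionally) are min-max normalised to an abnormality score
$a(t) = (e(t) - \min e)/\max e$ and a regularity score $s(t) = 1 - a(t)$;
constant error series score $s \equiv 1$. The regularity series then takes
the same forecaster → smoothed error → dynamic threshold path as an SEEG
channel, with intervals in frame indices and `modality = "video"`.
Precomputed regularity scores can be supplied as CSV, bypassing the
autoencoder. Desk-scale defaults (64×64 input, temporal depth 10, 8/12
filters) train in minutes on one CPU; they are a structural stand-in for the
480p/30 fps scale, not a performance claim.

## What the synthetic world emulates — and what it does not

Patient recordings cannot ship with the package, so every stage is exercised
on a seeded generator whose choices are fixed once and documented here:

* **Background**: band-limited oscillations plus AR(1) noise (innovation sd
  0.4, coefficient 0.9) whose standard deviation drifts ±50% at 0.005 Hz.
  Band amplitudes follow log-normal envelopes (band power in real EEG is
  classically log-normal): tonic bands at depth 0.5 / 20 s, and one bursty
  alpha/spindle-range band at depth 1.2 / 3 s.
* **Artifacts**: transient broadband bursts (2/min, 1–5 s, 0.75–2× the
  background RMS, a continuum of magnitudes). Monitored patients move, and
  the emulated workflow applies no artifact rejection; these bursts are what
  give a global mean + 2 SD threshold its false positives.
* **Events**: 4 Hz spike-wave trains (Gaussian-derivative spikes, σ = 5 ms,
  per-discharge amplitude jitter 0.3) with a broadband ictal component at
  0.6 of the rhythmic RMS — ictal onsets carry low-voltage fast activity
  that no forecaster predicts one step ahead, which is what makes events
  prominent in residual space. Total event RMS is `amplitude_gain` (default
  5) times background RMS, ramping over the first 25% of the event.
  Durations 5–15 s; 1–3 events per patient, placed in the later 60% of the
  record (training uses the opening minutes). Discharges are *focal*:
  channel 1 of each patient carries full amplitude, other channels a
  U(0.15, 0.5) projection.
* **Families** (for crossover experiments): two spectral families share
  their tonic bands and differ in the bursty band's centre frequency
  (10 vs 16 Hz), with ±1% frequency and ±10% amplitude jitter per patient.
  A matched forecaster notches the bursty band out; a foreign one leaks it,
  which is the patient-specificity signature the crossover harness measures.
* **Video**: regularity traces near 1 with noise sd 0.02, true events as
  deep drops (0.8) and nurse-visit-like nuisance dips as shallow drops
  (0.3, excluded from truth by design so false-positive behaviour is
  measurable). Raw synthetic video frames are used only in small fixtures;
  traces stand in at benchmark scale.

A green benchmark therefore establishes that the *mechanisms* behave as
described — dynamic beats static on precision when the noise floor drifts
and artifacts are present, crossover inflates false positives, pooling can
only add sensitivity — on a world with these statistics. It does not
establish clinical performance: the waveforms are statistical stand-ins, not
biophysics; channel counts are 2, not ~150; and real inter-patient
variability is far richer than two jittered spectral families. The
directional margins on the benchmark are modest by construction; they are
reported by the test suite, not tuned.

## Numerical choices and degenerate inputs

* Filtering uses reflect padding and one forward convolution with exact
  group-delay compensation; the stop-band attenuation asserted in tests is
  computed from the kernel's directly evaluated frequency response, not
  assumed.
* A constant series scales to all zeros (the open interval $(-1,1)$ cannot
  be honoured at zero range); a constant training segment yields an
  order-0 AR model predicting the mean; a zero-spread threshold window
  returns a no-anomaly decision; an all-constant error series yields no
  detections under either threshold.
* LSTM training restores the best-validation-epoch weights at early stop
  and halves the learning rate after each non-improving epoch while waiting
  out the patience window; with a fixed seed, training is bit-reproducible
  single-threaded, and model checkpoints round-trip losslessly.
* EDF I/O uses 16-bit integer records (1 s per record, padding the final
  record with the last value when necessary); round-trip accuracy is the
  16-bit quantisation of the physical range. No EDF or image package exists
  in the deployment environment, so the EDF subset reader/writer and a PGM
  frame reader are implemented here; frame directories may also be CSV
  grids.
* `match_events()` uses the any-overlap rule; one prediction covering
  several events counts once as a true-positive prediction but detects each
  event. Interval-level (not sample-level) counting is used throughout.

## Limitations

* The AR baseline, not the LSTM, powers the large benchmarks (CPU budget);
  the LSTM is validated on clean periodic channels (held-out MAPE below 5%)
  and smoke-tested inside the full pipeline.
* The video autoencoder is desk-scale; its regularity scores on real 480p
  footage would require the full-scale configuration and far longer
  training.
* Streaming is emulated: detection is causal past the training segment and
  window-by-window evaluation is proven equal to the batch result in the
  test suite, but no real-time I/O loop is provided.
* Alarm escalation, multi-camera fusion, montage/re-referencing and artifact
  rejection are out of scope.
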