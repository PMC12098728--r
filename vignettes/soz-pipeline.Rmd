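---
title: "Methods: interictal iEEG features and SOZ classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interictal iEEG features and SOZ classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In drug-resistant focal epilepsy, surgery aims to remove the epileptogenic
zone. The clinical surrogates available before and after surgery are the
seizure onset zone (SOZ) — electrodes judged to initiate seizures — and the
resection zone (RZ), the tissue actually removed. `sozpipe` implements an
analysis pipeline that asks: how well can SOZ/RZ membership of an
intracranial EEG (iEEG) channel be predicted from *interictal* (between-
seizure) signal features alone, and which feature families carry that
information?

Each channel of a 30-minute awake interictal recording sampled at 1000 Hz
is summarized by 45 features in four families:

* **Spikes (2)** — rate (events/min) and mean amplitude of automatically
  detected epileptiform discharges.
* **HFOs (2)** — rate and mean amplitude of 80–250 Hz high-frequency
  oscillations.
* **Band power (9)** — Welch power spectral density (2-s Hann windows, 50%
  overlap), averaged within nine bands (1–4, 4–8, 8–12, 15–25, 35–50,
  70–110, 130–170, 190–230, 250–290 Hz), in dB. The bands skirt 60 Hz and
  its harmonics.
* **Functional connectivity (32)** — amplitude envelope correlation (AEC)
  and phase locking value (PLV) in the eight bands above 4 Hz, reduced to
  two per-node graph metrics each (normalized node strength, eigenvector
  centrality): 2 measures × 8 bands × 2 metrics.

AEC and PLV both derive from the analytic signal of the band-passed epoch:
for channels $x, y$ and band $f$, the envelope is $|H[x(t,f)]|$ and the
phase $\phi_x(t,f)$. AEC is the Pearson correlation of the two envelopes;
PLV is $|\,\mathrm{mean}_t\, e^{i(\phi_x - \phi_y)}|$. Recordings are cut
into 12-s non-overlapping epochs (150 per 30 minutes); epochs with any
unfiltered sample above 3000 µV are excluded, 100 of the clean epochs are
drawn at random, and per-epoch connectivity matrices are averaged. No
thresholding is applied to the connectivity values.

## Preprocessing

Channels flagged as bad (expert review in practice; explicit flags here)
are dropped. Power-line noise at 60 Hz and its first five harmonics
(120–360 Hz) is removed by spectral interpolation: within ±1 Hz of each
target frequency the full-record amplitude spectrum is replaced by linear
interpolation between the flanking bins, phase retained. This was chosen
over notch filtering because it does not ring in the time domain and
leaves distant bands untouched (verified to <0.1 dB). Signals are then
re-referenced to the common average. The harmonic count is interpreted as
*five harmonics above the fundamental*; the alternative reading (60 Hz as
the first harmonic) would remove one target fewer.

## Classifier evaluation

Classifiers (gaussian-kernel SVM, cubic-kernel SVM, random-forest
ensemble; further kinds pluggable via a fit-function argument) are scored
by ROC AUC under three cross-validation designs:

* **node-level 4-fold** — channels partitioned freely; optimistic, since a
  patient's channels appear in both train and test;
* **patient-level 4-fold** — patients partitioned into folds as equally as
  possible ({6,6,7,7} at 26 patients); and
* **patient-level leave-one-out** — one fold per patient.

The 4-fold designs are repeated 10 times with fresh partitions; the paired
statistic for comparing feature subsets is the per-repetition *median* AUC
across folds, compared with a paired Wilcoxon signed-rank test and
Bonferroni correction. Patient-level designs assert on every fold that no
patient appears on both sides.

Class imbalance (SOZ channels are a small minority) is handled by scaling
the false-negative cost by the training-set negative:positive ratio.
Hyperparameters are selected by a sequential model-based search (Gaussian
process surrogate on normalized log-scale parameters, expected-improvement
acquisition) minimizing an internal stratified 3-fold loss (1 − AUC). The
evaluation budget is an argument: 300 evaluations reproduces the reference
design; the package tests use 5–8, which is sufficient for the synthetic
effect sizes.

Feature scaling divides each column by its maximum absolute value. Two
modes exist: `scaling = "train"` (default) fits the scale on the training
rows of each fold, which is leakage-safe; `scaling = "all"` fits once on
all rows, reproducing the whole-cohort convention some studies use. Both
are tested; the default is the conservative one.

## Statistics

* `group_feature_comparison()` — per feature, per patient mean over SOZ vs
  non-SOZ channels, paired Wilcoxon across patients, Bonferroni over the
  45 features. The signed-rank test drops zero differences; for n ≤ 14 the
  exact two-sided null is computed by dynamic programming over midranks
  (so tied differences are handled exactly), larger n uses the normal
  approximation.
* `random_subset_curve()` — AUC as a function of feature count k for
  random subsets (size uniform on 1..45, then columns uniform), fitted
  with the saturating power law AUC(k) = a − b·k^(−c) via
  Levenberg–Marquardt least squares. This form is monotone for b, c > 0
  and matches the observed plateau; a log-linear fallback with a warning
  covers non-convergence. The subset-size distribution is a package
  choice; nothing hinges on it.
* `optimal_operating_point()` — the intersection of the piecewise-linear
  ROC with the line TPR = 1 − FPR, by linear interpolation between
  vertices; a segment lying on the line yields its midpoint. The decision
  threshold is interpolated alongside (taking the finite endpoint where a
  vertex threshold is infinite).
* `rz_enrichment_test()` — thresholds SOZ-classifier scores at the optimal
  operating point; false positives are non-SOZ channels called positive.
  The observed percentage of false positives inside RZ-but-not-SOZ is
  compared to a null built by drawing the same number of channels
  uniformly from *all* non-SOZ channels (including non-RZ ones) 5000
  times; z is two-sided against the null's normal approximation. Zero
  false positives are reported as an undefined statistic rather than 0%.
* `fc_stability()` / `epoch_count_analysis()` — how many epochs are needed
  for stable connectivity and for classifier performance; the epoch-count
  analysis reuses per-epoch connectivity matrices and keeps the channel
  partition fixed across counts within a repetition so that only the
  epoch budget varies.

## The synthetic cohort generator

Patient iEEG cannot be shared, so every stage is validated against
`generate_cohort()`, which produces recordings with known ground truth.
Per channel the signal is a sum of:

* 1/f²-shaped Gaussian background noise (25 µV RMS; spectrum flattened
  below 1 Hz);
* **structured background connectivity**: every analysis band has a shared
  amplitude-modulated narrow-band source; channel *i* couples to it with a
  random weight drawn from U(0, `band_coupling_bg`). Real cortical
  recordings show heterogeneous, temporally stable connectivity in every
  band, and the 25-vs-150-epoch stability property presumes it; a
  generator with independent channels would have no stable structure to
  recover. Band-source amplitude tracks the in-band background level, so
  low-frequency rhythms are large and gamma rhythms small, as in cortex;
* an extra gamma-band (70–110 Hz) source shared by SOZ channels with
  coupling `gamma_coupling_soz` — the injected epileptogenic-network
  effect. Two mechanisms are available: `"shared_source"` (one source,
  raising AEC *and* PLV together) and `"shared_envelope"` (a common slow
  envelope on independent carriers, raising AEC only). The second exists
  because several validation questions require an envelope-specific
  effect, e.g. "do AEC features beat PLV features when only envelope
  coupling is injected?";
* injected events at class-dependent Poisson rates: biphasic
  difference-of-Gaussians spikes (20–70 ms, 100–400 µV, random polarity)
  and Tukey-windowed HFO bursts (100–200 Hz, 30–80 ms, 10–40 µV), all
  logged in a provenance table for oracle tests;
* 60 Hz line noise with five harmonics (amplitude 1/k); and
* rare 1–5 s rectangular ±4000 µV artifact segments on one channel,
  exercising the epoch-exclusion rule.

Envelope fluctuations use a smoothed Gaussian modulation with ~0.15 s
correlation time — fast enough that a 12-s epoch contains tens of
independent envelope samples, as gamma envelopes do in cortex. Identical
seeds reproduce output bit for bit; per-patient seeds derive from the
cohort master seed.

Two subtleties matter when building *null* (effect-free) conditions from
the generator. First, an effect-free cohort must set the zone couplings
to zero, not merely equal: a shared source given to the SOZ group at the
same strength as the global one still produces a group-size asymmetry in
node strength (three channels sharing a source accumulate fewer
correlated edges than twenty). Second, chance-level classification should
be assessed in expectation: at the scaled-down cohort sizes used for
testing, a single cohort's node-level CV AUC has a standard deviation
near 0.1 — partly fold noise, partly the ability of node-level CV to
exploit chance within-patient correlations (the same optimism that
motivates patient-level validation). Null checks therefore average over
several generated cohorts or label shuffles, and label shuffles are done
*within* patients so that per-patient base rates — which a node-level
classifier can read off patient identity — are preserved.

What the generator does **not** emulate: biophysical neural-mass dynamics,
ictal activity, electrode geometry and volume conduction, non-stationary
state changes (sleep/wake), or realistic artifact morphology. Passing
tests therefore demonstrate that the pipeline recovers known structure of
this statistical kind, not clinical performance on real iEEG.

## Detector stand-ins

The reference spike and HFO detectors are external tools with thresholds
in an unavailable supplement; the package ships documented stand-ins with
the same output contract (per-channel rates and amplitudes):

* **Spikes** — 10–60 Hz band; candidate peaks above `amp_mult` (5) times
  the channel MAD with maximum slope above `slope_mult` (4) times the MAD
  of the first difference within ±50 ms; greedy refractory suppression
  (200 ms) keeps the strongest peaks, which makes detection counts
  provably non-increasing in the thresholds.
* **HFOs** — 80–250 Hz band; sliding 10-ms RMS must exceed `thr_scale`
  (2) × the 95th-percentile baseline for ≥10 ms with ≥4 rectified peaks
  above half the event threshold. A *baseline* percentile times a scale
  factor is used rather than a single extreme percentile because the
  latter self-masks once events occupy more than its tail fraction of the
  recording.

Defaults were calibrated on simulated nulls so that white-noise false
detections stay below 1/min (the high-specificity regime), with ~80–90%
sensitivity to the generator's injected events.

## Numerical choices

* Band-pass filtering: windowed-sinc FIR (Hamming; order 3.3·fs/transition,
  transition 25% of the low edge, capped at 4000 taps), applied two-pass
  (forward–backward) in the frequency domain by multiplying the spectrum
  with |B(f)|². This is exactly zero-phase, doubles the stopband
  attenuation, and is O(n log n) on 30-minute records; edge handling is
  circular, negligible for long signals.
* Analytic signal: FFT construction, vectorized across channels; epochs
  are mirror-padded by one full epoch length on each side before the
  transform and trimmed after.
* Eigenvector centrality requires a non-negative matrix; negative AEC
  entries are clipped to zero for this metric only (the count is recorded
  on the result), while node strength keeps them, consistent with the
  no-thresholding rule.
* Per-epoch AEC values that are undefined (zero-variance envelope) are
  excluded from the epoch average, not zero-filled.
* Per-patient 0–1 rescaling of graph features is applied separately per
  feature; a constant feature maps to all zeros.
* Cross-patient scaling uses the maximum *absolute* value; all features
  are non-negative after the earlier rescaling, so signed and absolute
  maxima coincide in practice.
* Artifact flagging operates on the preprocessed but pre-band-pass signal
  ("unfiltered" relative to the band decomposition).

## Problem sizes

Full-scale defaults mirror the study conditions (26 patients, 41–121
channels, 30 minutes, 100 epochs, 300 search iterations). The test suite
and the acceptance script run scaled-down cohorts chosen as the smallest
sizes at which the injected effects are comfortably detectable: 5–6
patients with 10–14 channels and 4-minute recordings, 15 connectivity
epochs, and search budgets of 5–8 evaluations. The connectivity-stability
analysis alone uses the full 16-channel, 30-minute, 150-epoch condition,
since the property under test is specifically about epoch counts.

## Known limitations

* The detectors are contract-compatible stand-ins, not re-implementations
  of the published detectors; absolute rates are not comparable to theirs.
* The generator's SOZ effect is a single gamma-band coupling plus event-
  rate elevation; real epileptogenic networks are broader-band and
  non-stationary.
* Patient-level AUCs on small synthetic cohorts are noisy; orderings
  (node-level ≥ patient-level, AEC > PLV under envelope-specific effects)
  are reproduced across seeds, but their magnitudes are not meaningful.
* EDF input is not supported; recordings enter as delimited matrix + JSON
  sidecar (or in memory).
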