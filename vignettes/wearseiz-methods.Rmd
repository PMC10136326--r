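---
title: "Methods: multimodal wearable seizure detection in wearseiz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal wearable seizure detection in wearseiz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearseiz)
```

# Overview

`wearseiz` implements a semi-automated seizure-detection pipeline for
wearable recordings of people with focal epilepsy: a behind-the-ear EEG
(bte-EEG) detector, a heart-rate based ECG detector, decision-level 'OR'
fusion, event-based scoring, and a review-export/ingest workflow in which
human readers relabel only the algorithm's alarms. Because clinical
wearable datasets are access-restricted, the package also contains a seeded
synthetic-recording generator that reproduces the statistical structure the
detectors rely on; every module is tested against it.

This vignette documents the models and conventions, the tunable parameters
and their defaults, what the generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

# Time convention

All modules exchange times as float seconds from the start of the
recording, and all intervals are half-open `[start, end)`. This makes
"overlap" unambiguous (touching intervals do not overlap) and durations
additive; annotation CSVs and EDF files are read once at the boundary and
never re-read downstream.

# The bte-EEG detector

The two channels are a cross-head and an ipsilateral (relative to the
seizure-onset hemisphere) derivation. Both are conditioned with a
zero-phase 4th-order Butterworth band-pass, 0.5–35 Hz — zero-phase because
phase distortion would smear the rhythmic ictal patterns the features look
for; the band matches what reviewers see on screen.

The signal is cut into 2 s windows with a 1 s hop, and each window is
described by 67 features in four families:

* **time-domain, 12 per channel** — mean absolute amplitude, RMS, SD,
  peak-to-peak, line length, zero crossings, skewness, kurtosis, the Hjorth
  triple (activity, mobility, complexity), and mean nonlinear (Teager)
  energy;
* **frequency-domain, 8 per channel** — relative band powers in delta
  (0.5–4 Hz), theta (4–8), alpha (8–13) and beta (13–35), log total power,
  95% spectral edge, peak frequency, spectral centroid (all from the
  window periodogram restricted to 0.5–35 Hz);
* **entropy-derived, 4 per channel** — spectral entropy, sample entropy,
  permutation entropy (order 3), amplitude-histogram entropy;
* **cross-channel asymmetry, 19** — per-band log power ratios and
  normalized differences, total-power/RMS/line-length log ratios,
  zero-crossing and Hjorth differences, Pearson correlation, maximum
  normalized cross-correlation within ±50 ms and its lag, spectral-edge and
  peak-frequency differences.

That is 24 + 16 + 8 + 19 = 67. The exact composition is frozen in
`eeg_feature_names()`, which also marks the subset invariant under common
amplitude rescaling of both channels (relative powers, entropies, shape and
asymmetry measures); the invariance is property-tested. Conventions for
degenerate windows: an all-zero window has uniform relative band powers
(0.25 each), spectral entropy 1, and zero for location/shape features —
flat data carries no band preference and flags nothing.

Sample entropy (m = 2, r = 0.2 SD) is computed on the window decimated by a
factor 2: at wearable sampling rates neighbouring samples are strongly
correlated, which saturates the lag-1 embedding; the decimated estimate is
more discriminative for theta-range rhythms and cheaper.

The window classifier is an RBF-kernel SVM (via `e1071`/libsvm) with the
feature standardization fitted on the training set and stored inside the
model object, and inverse-frequency class weights for the heavy
background/seizure imbalance. Hyperparameters were left at `cost = 1`,
`gamma = 1/67` (overridable); the decision threshold is 0. A training
window is labelled positive when at least half of it overlaps a
ground-truth seizure.

**Post-processing.** A detection is valid only when at least 8 positive
windows occur within 10 consecutive segments. A qualifying group starting
at window index g (0-based) contributes the span
`[g·hop, (g + 10)·hop)`; overlapping or contiguous spans are merged. This
span convention was chosen because it makes the minimum possible alarm
exactly `10 × hop = 10 s`; the alternative first-to-last-sample reading
would give 11 s. The rule's consequences are verified exhaustively: the
test suite compares the implementation against a naive group-enumeration
oracle on all 2^14 binary sequences of length 14, and
`scripts/acceptance.R` recomputes the 10 s minimum by enumeration. This
group rule is also what suppresses brief artifact bursts: a 2–5 s
high-amplitude transient can flip at most ~6 consecutive windows and can
never satisfy 8-of-10.

# The ECG detector

Heart rate is derived from an ensemble of R-peak detectors. Two
implementations ship: a derivative-threshold detector in the Pan–Tompkins
tradition (band-pass 5–15 Hz, differentiate, square, 150 ms moving-window
integration, adaptive per-chunk threshold) and an amplitude-adaptive
local-maximum detector (running-median baseline removal, per-chunk
threshold). Both refine candidates to the band-passed maximum and enforce
a 250 ms refractory period. The ensemble pools all detectors' peaks,
clusters them within 100 ms, and keeps centroids supported by a strict
majority — the ensemble contract matters here, not the identity of the
member algorithms, and more detectors can be added.

Instantaneous heart rate is 60/RR at each beat midpoint after rejecting
implausible beats (RR outside 0.24–3 s or beat-to-beat change above 35%,
standard HRV-cleaning practice; both configurable), optionally followed by
a short running-median smoother over 5 beats to suppress residual
detection jitter.

Features are computed on 60 s windows with a 10 s hop — the autonomic
response evolves over tens of seconds, an order of magnitude slower than
the EEG patterns. Seven features per window: mean HR, HR range,
least-squares HR slope (BPM/s), SD of the R-R intervals, RMSSD, pNN50, and
the ratio of window-mean HR to a trailing 5-minute baseline. Windows with
fewer than 5 beats are flagged missing and excluded from classification.
Training labels are extended by ±30 s around each seizure so the
classifier learns the slower peri-ictal pattern; the extension clamps at
the recording edges and merges overlapping results (extending twice by
30 s equals extending once by 60 s — asserted). Each positive window
contributes its full 60 s span to event formation, so ECG alarms last at
least 60 s and grow in 10 s steps.

**Ictal tachycardia.** For each seizure the heart-rate increase is the
maximum HR inside `[onset, offset + 30 s]` minus the median HR in the 60 s
before onset. At least +20 BPM defines a *responder*, an increase in
(0, 20) an *intermediate* response, and no increase a *non-responder*. The
20 BPM threshold is the clinical criterion; the baseline estimator (median
of the pre-ictal minute) is this package's choice — the criterion itself
does not prescribe one, and a median resists brief pre-ictal artifacts.

# Fusion

The multimodal stream is the union of the unimodal alarms ('OR' — the
framework optimizes sensitivity). On overlap the bte-EEG segment is taken:
the ECG event is dropped entirely, including when a single long ECG event
spans several EEG events — the minimal reading of EEG priority. Whether
the non-overlapping tail of a partially overlapping ECG event should
instead be truncated and kept is genuinely unspecified; dropping the whole
event is implemented and noted here rather than silently guessed.
Touching-but-not-overlapping events both survive, per the half-open
convention. An experimental 'AND' strategy is deliberately out of scope.

# Scoring

Overlap for matching is any nonempty intersection — no minimum-overlap
fraction. Sensitivity is counted over *seizures* (detected/total) while
PPV is counted over *detections* (TP/(TP+FP)): one seizure can attract
several detections, so the two numerators differ, and both raw counts are
always exposed. FD/24h is `86400 · FP / D` with D the recording duration in
seconds. Ratios of the form 0/0 are returned as `NA` and listed in an
`undefined` field — silent zeros would corrupt stratified tables.

Reader scoring mirrors the semi-automated setting: the reader only ever
sees alarms, so seizures the algorithm missed are excluded from every
reader count; a TP requires both the reader label "seizure" and a
ground-truth overlap.

Cohen's kappa is computed from the marginal-product expected agreement;
the degenerate `p_e = 1` case (both raters constant on the same category)
yields kappa 1 when agreement is perfect. McNemar's test uses the exact
two-sided binomial tail when the discordant total is below 25 and the
continuity-corrected chi-squared statistic (via `stats::mcnemar.test`)
otherwise; the variant switch-over is this package's choice, as the common
practice when either variant might be underpowered or anticonservative.

# The synthetic generator

The generator is the package's substitute for restricted clinical data and
defines the conditions under which the pipeline is tested:

* **Background EEG** — zero-mean 1/f-weighted noise (flat below the 0.5 Hz
  passband edge), rescaled to an exact target SD, default 20 µV.
* **Ictal rhythm** — an amplitude-modulated sinusoid at a configurable
  frequency in the theta range (default 5 Hz, matching the
  temporal-lobe-dominated clinical picture), envelope ramping linearly
  from 0.3× to 1× of the target amplitude (default 60 µV) across the
  burst, with background-scale noise superimposed. It is injected on the
  cross-head channel and attenuated ×0.6 on the ipsilateral channel.
* **Artifacts** — EMG-band (20–35 Hz, inside the review passband)
  high-amplitude bursts of 2–5 s at a Poisson rate (default 10/h), placed
  outside a 30 s guard zone around seizures, tapered, stronger on the
  cross-head channel.
* **Heart rate** — a baseline (default 70 BPM) plus slow AR(1) wander
  (SD 1.5 BPM by default, ~400 s correlation time, winsorized at 2.75 SD —
  larger excursions would represent activity bouts, which the artifact
  model covers) plus a trapezoidal peri-ictal excursion: linear rise over
  `hr_ramp_s` (default 20 s) from onset, plateau to offset, exponential
  recovery with a 60 s time constant. The default +25 BPM puts simulated
  responders clearly past the 20 BPM criterion. Negative values simulate
  mild ictal bradycardia and are the generator's non-responder condition
  (−10 BPM in the test cohorts); their ramp is placed just before onset,
  as bradycardic responses emerge around electrographic onset. A flat
  profile cannot be recovered as "no increase" by a max-minus-median
  estimator under any wander, which is why non-responders are modelled as
  a mild dip rather than exactly zero change.
* **ECG** — beat times are stepped through the heart-rate profile (the
  interval after a beat at t is 60/HR(t)), and a fixed PQRST template of
  Gaussian components is placed at each beat, plus white measurement noise
  (0.02 mV). Template synthesis was chosen over a dynamical ECG model
  because it yields exact ground-truth R-peak times for detector oracle
  tests.

Everything is a pure function of `(config, seed)`; identical seeds give
bit-identical recordings.

**What the generator does not emulate** — and hence what passing tests do
not show about clinical data: realistic head-volume conduction and
electrode physics, the heterogeneity of real focal ictal morphologies
(many of which are *not* clean theta rhythms on a two-channel montage),
electrode-movement and impedance artifacts with seizure-like rhythmicity,
ECG morphology changes (arrhythmias, ectopy) beyond rate changes, and the
co-occurrence statistics of artifacts with real seizures. The synthetic
cohort is a correctness harness for the pipeline's machinery, not evidence
of clinical performance; clinical sensitivity/false-alarm figures can only
come from real wearable datasets.

**Problem sizes.** The packaged test cohorts use 10 recordings of 600 s at
250 Hz with two 40 s seizures each — large enough that every stage
(windowing, training, post-processing, scoring) operates in its intended
regime, and small enough to iterate on. Clinical recordings are hundreds of
hours; nothing in the code depends on the recording length beyond memory.

# File formats

Signals travel as EDF (16-bit, 1 s data records, physical scaling per
channel; symmetric digital range so an exact zero survives round trip;
worst-case quantization error is half of range/65534). The EDF layer is
deliberately minimal — no EDF+ annotation blocks, no BDF — and channel
roles are assigned from labels by a configurable regex table because label
dialects vary between vendors. Annotations and reader labels are plain
CSV with validated headers; review packages export display metadata (10 s
EEG window, 10 min heart-rate window, 70 µV/cm) so any viewer can honour
the review setup.

# Known limitations

* The 67-feature catalogue spans the four stated families but is this
  package's own fixed selection; other implementations of the same
  pipeline family use different members within the same families.
* The SVM is patient-independent as tested (leave-one-recording-out);
  patient-specific training is possible through the same functions but is
  not exercised by the shipped cohorts.
* The ECG classifier shares the SVM contract with the EEG side via a
  config switch rather than implementing a second classifier family.
* Reader experiments require humans; the package scores reader label
  files and computes agreement statistics but cannot generate reader
  behaviour.
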