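---
title: "Detecting tremor in motion-capture kinematics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tremor in motion-capture kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorkit)
```

## The problem

Optical motion capture in a movement-disorders clinic produces, per
trial, trajectories of ~60 reflective markers at 120 Hz (x, y, z in mm).
Clinicians annotate tremor presence or absence separately for 16 body
extremities (head, shoulders, thorax, pelvis, and left/right hand,
distal/proximal arm, foot, distal/proximal leg). `tremorkit` provides six
pipelines that reproduce that binary judgment from the kinematics, plus
the machinery to evaluate them.

The shared signal model: pathological tremor is a narrowband, nearly
sinusoidal oscillation, typically 4–12 Hz; voluntary movement (reaching,
pointing, walking) concentrates below 2–3 Hz; optical marker jitter
contributes broadband noise that grows in relative importance at high
frequencies. Every pipeline therefore works in the frequency domain and
differs mainly in *which* kinematic signal is transformed and *how* peaks
are summarized.

## The synthetic data generator

Clinical recordings cannot be redistributed, so the package ships a
seeded simulator whose output exercises every stage. Per marker $m$ and
axis $a$:

$$x_{m,a}(t) = b_a + \sum_k A_k \sin(2\pi f_k t + \phi_{m,a,k})
  + s_m A_T \sin(2\pi f_T t + \psi_{m,a}) + \varepsilon(t)$$

* **Voluntary movement**: 1–3 sinusoids below 3 Hz. Rest-like trials use
  0.1–1 Hz components of at most ~1 mm each (postural drift); movement-like
  trials use 0.5–2.8 Hz components of 10–60 mm each (reaching-scale
  displacements).
* **Tremor**: a single sinusoid with frequency shared by all markers of
  an extremity, per-marker amplitude scale $s_m \sim U[0.5, 1]$ (distal
  markers tremble most), optional single harmonic (off by default —
  neurologic tremor is highly sinusoidal). Amplitudes are drawn
  log-uniformly from 0.2–10 mm by default, straddling the 0.1 mm clinical
  rule threshold and the ~1 cm bedside rating anchor.
* **Jitter**: white Gaussian noise, sd 0.05 mm — the scale of optical
  marker noise; white is the conservative choice absent a measured
  spectrum.
* **Geometry**: baselines are drawn from 500–1500 mm per axis, placing
  extremities at realistic distances from the capture-volume origin
  (this matters for the magnitude-projection pipelines, below).
* **Durations** follow the clinical distribution: Normal(27 s, 9 s)
  truncated to [3, 92] s. Sampling is 120 Hz; three markers per
  extremity.

`simulate_dataset()` fixes the positive count to `round(n × prevalence)`
(default prevalence 0.32, echoing the clinical annotation base rate) and
draws everything else from a single root seed, so datasets are
bit-reproducible. Tremor-absent recordings are split 50/50 between
rest-like and movement-like trials so that classifiers must *reject*
large voluntary motion rather than respond to any spectral energy.

**What the generator does not emulate**: intermittent or
amplitude-modulated tremor, dystonic/dyskinetic waveforms, task-shaped
trajectories (pointing paths, gait cycles), articulated-skeleton
correlations between extremities, and marker occlusion patterns. Passing
the synthetic suite therefore demonstrates correctness of the signal
processing and the expected behaviour of the classifiers under the
stated spectral assumptions — not clinical-grade performance.

## Pipeline A1: velocity spectral peaks

Per marker: zero-phase 4th-order Butterworth low-pass at 20 Hz,
centring, then a Savitzky–Golay derivative filter (order 3, window 11
samples ≈ 92 ms) for smooth velocities; the filter passes analytic
ramp/sinusoid derivative oracles to <2%. Per-axis Welch PSDs (Hamming,
segments of min(512, n) samples, 50% overlap) are combined as
$\sqrt{P_x^2 + P_y^2 + P_z^2}$, log-scaled, Savitzky–Golay smoothed
(order 3, 9 bins) and returned to the linear scale.

Descriptors of the in-band maximum: centre frequency, interpolated 3 dB
border frequencies and bandwidth, border power levels, the fraction of
total power inside the 3 dB band, and a sinusoid-equivalent amplitude
$\sqrt{2 P_{peak} \cdot ENBW}$ (ENBW = the Hamming window's equivalent
noise bandwidth). Rules: a valid peak is tremor if `BW ≤ 2 Hz`,
`|HI_POWER − LO_POWER| ≤ 3 dB` and `F_CENTER ≤ 10 Hz`; the passing
marker with the largest amplitude represents the extremity
(winner-take-all; exact ties go to the first marker).

Two details were genuinely open and deserve their rationale:

* **Search band.** The peak search runs over 3.5–20 Hz
  (configurable, `a1_control(band = )`). With a lower edge below ~3 Hz, a
  large voluntary sinusoid at, say, 2 Hz forms a narrow, symmetric,
  sub-10 Hz velocity peak and the rules would call it tremor; the
  velocity domain amplifies this (velocity amplitude scales with
  frequency × displacement, and reaching displacements are tens of mm).
  3.5 Hz is the same "unlikely to be neurologic" bound the amplitude
  pipeline's rules use. Band-edge maxima have no left 3 dB crossing and
  are marked invalid, so sub-band energy cannot leak in as a verdict.
* **Symmetry quantification.** "Symmetric power about the peak" needs a
  number. Border powers are evaluated at mirrored offsets of one full
  3 dB bandwidth below/above the *interpolated* 3 dB midpoint. The
  midpoint tracks the true line centre even when it falls between
  frequency bins (probing around the maximum *bin* makes the indicator
  alias with bin alignment), a symmetric peak scores ~0 dB, and a peak
  riding a one-sided low-frequency shoulder scores large. The 3 dB
  tolerance is exposed in `a1_control()`.

## Pipeline A2: displacement amplitude peaks

Per axis and marker: zero-phase 4th-order Butterworth high-pass at 2 Hz,
then the single-sided FFT amplitude spectrum ($2|X|/N$, mm; raw length,
no padding). All spectra of an extremity are combined by elementwise
maximum — "the most severe tremor at each frequency" — then smoothed
with a 3rd-order Savitzky–Golay filter (9 bins, clamped at zero since
the filter's negative lobes can undershoot at edges). Local maxima
(strictly greater than both neighbours, plateaus taking their leftmost
point, mirroring common `findpeaks` defaults) are ranked by amplitude;
the dominant peak gets prominence (highest-connecting-saddle definition)
and half-prominence width.

Rules: present iff `3.5 ≤ F_CENTER ≤ 10 Hz` (inclusive — the exclusion
is stated for peaks *below* 3.5 or *above* 10 Hz) and
`AMPLITUDE_MM ≥ 0.1 mm` (inclusive).

**Amplitude readout.** Peak *location*, prominence and width are
measured on the smoothed spectrum, but `AMPLITUDE_MM` is read from the
raw aggregate in the located peak's neighbourhood. A Savitzky–Golay
smoother (order 3, window 9) scales an isolated one-bin spectral line by
59/231 ≈ 0.26, so an amplitude read off the smoothed spectrum would
understate a clean tremor line by ~4× and make the 0.1 mm clinical
threshold meaningless; the raw readout recovers bin-aligned noise-free
amplitudes within the documented 20% window-leakage tolerance.

## Pipeline B: generic spectral features

Per marker, the position magnitude $r(t) = \sqrt{x^2+y^2+z^2}$ reduces
three axes to one signal. The mean is subtracted, then an order-80
Hamming-window FIR band-pass (1–20 Hz) is applied with its 40-sample
group delay removed (symmetric taps, linear phase), and the signal is
decimated 120 → 40 Hz — no extra anti-alias filter is needed because the
passband ends at the new Nyquist. The explicit mean subtraction is
needed because an order-80 FIR at 120 Hz has a ~5 Hz transition width
and leaves a DC gain of ≈0.39, while the magnitude signal carries a
baseline offset of ~1 m.

Welch PSD: 120-sample Hamming windows advanced by 10 samples (3 s
windows, 2.75 s overlap), giving a 120-point two-sided PSD with
40/120 = 0.33 Hz bins. A discrete Gaussian kernel (σ = 1 Hz = 3 bins,
truncated at ±4σ, renormalized, applied circularly on the two-sided
spectrum) sharpens dominant frequencies for the classifier. The first
61 values (DC–20 Hz) form the feature vector; extremity vectors are the
arithmetic means across markers (smoothing precedes averaging).
Recordings shorter than 3 s are rejected, not padded — that is the
minimum clinical trial length.

**Origin sensitivity** is a documented property, not a bug: the
magnitude projects motion onto the marker's position vector, so tremor
orthogonal to it is attenuated (the test suite demonstrates a ≥10×
PSD ratio between aligned and orthogonal tremor). This is one reason
the A pipelines remain available.

## Classifiers

* `a1r`/`a2r`: the fixed rules above; "fitting" stores thresholds only,
  and scores are degenerate {0, 1}.
* `a1s`/`a2s`: the engineered descriptor sets (9 and 4 columns) plus a
  `NO_PEAK` indicator, fed to an RBF-kernel SVM. Rows whose extraction
  found no valid peak are imputed to zeros with `NO_PEAK = 1`,
  preserving the "no peak" information without dropping records.
* `b1`: the 61-point vector to an SVM (RBF default, linear available);
  `b2`: the same vector to XGBoost (100 rounds, depth 6, logloss
  evaluation metric, single thread for reproducibility).

For the SVM pipelines, amplitude- and power-valued features are
log-compressed before standardization (train-set mean/sd; constant
columns keep scale 1). This is the conventional dB representation:
spectral magnitudes span many orders of magnitude across rest-like and
movement-like trials, and on the raw scale an RBF kernel at default cost
underfits badly. No hyperparameter search is performed anywhere —
defaults are `cost = 1`, `gamma = 1/d` on standardized features.

SVM scores are the logistic squash of the signed margin distance, so
they are deterministic, monotone in the decision value, and thresholding
at 0.5 reproduces the SVM's class boundary exactly. (Platt-style
probability calibration adds an internal random cross-validation and can
disagree with the class boundary on separable data.) The decision
threshold (default 0.5) is a model field; ROC/PRC curves expose the full
operating range for `b1`/`b2`.

## Evaluation

Stratified k-fold (default 5) assignment deals each class's shuffled
records round-robin, so per-fold class counts are within one record of
proportional; 2272 records yield the familiar 1818/454-record train/test
folds. Folds are assigned at the (recording, extremity) record level; a
grouped-by-patient option is a natural extension but is not the default,
matching how such record-level evaluations are usually reported.

Metrics come from the confusion counts; specificity is the standard
TN/(TN+FP). A variant TN/(TN+FN) appears in some write-ups —
`compute_metrics(specificity_as_printed = TRUE)` reproduces it for
audit, but the standard form is the default because reported specificity
values in this literature are consistent with it. Ratios that become 0/0
(e.g. no predicted positives in a fold) return 0 with a warning. AUROC
is trapezoidal; AUPRC uses step interpolation (average precision). Mean
curves are vertically averaged on a common 101-point grid with ±1 SD
bands. Sample SD (n−1) is used across folds.

## The standard benchmark and expected results

`tremor_benchmark()` is the package's fixed reference condition: n = 400
recordings, prevalence 0.32, tremor amplitudes log-uniform 0.5–10 mm,
tremor frequencies uniform 4–10 Hz, clinical duration distribution. The
frequency band is the clinically plausible one that the legacy rules
encode: both rule pipelines *by construction* classify peaks above
10 Hz as non-neurologic, so benchmark positives above 10 Hz would
measure that design choice rather than detection quality (the
generic-feature pipelines learn such frequencies without complaint —
one genuine advantage of trainable classifiers). Under these conditions
all six pipelines reach F1 ≥ 0.9 under 5-fold cross-validation; the
acceptance script recomputes this end to end in under a minute on one
CPU, which is why n = 400 and three markers per extremity were chosen.

## Numerical choices and degenerate inputs

* Zero-phase filtering pads signals by odd reflection (about 3 filter
  time constants) before forward–backward filtering; without padding,
  start-up transients at offsets of ~1 m dwarf mm-scale tremor.
* Welch estimates drop a final partial segment; spectra are density
  normalized (power/Hz) — any consistent scaling works for
  classification, this one keeps the amplitude conversions honest.
* Flat or all-zero spectra, band-edge maxima, and monotone aggregate
  spectra yield `valid_peak = FALSE`, which the rules map to "absent"
  and the feature matrices impute to zeros with the `NO_PEAK` flag.
* TRC gaps are NA on read; gaps ≤ 0.25 s are linearly interpolated,
  longer gaps reject the marker with a warning (delivered clinical files
  are assumed already interpolated; this guards degraded input).
* Exact winner-take-all amplitude ties go to the lowest marker index;
  plateau peaks take their leftmost sample — both for determinism.

## Known limitations

* Tremor above 10 Hz and below ~3.5 Hz structurally escapes the rule
  pipelines; only `b1`/`b2` can learn it.
* The B-pipeline magnitude projection is origin- and posture-dependent.
* No probability calibration, no hyperparameter search, no
  patient-grouped cross-validation, no time-resolved (within-recording)
  tremor tracking, and no modelling of dystonia/dyskinesia look-alikes.
* The default 60-marker montage is illustrative; real montages are
  site-specific and should be supplied via the marker-map YAML.
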