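# tremorkit

Tremor — an involuntary, rhythmic, oscillatory movement of a body part —
is a cardinal sign of Parkinson's disease, essential tremor and related
movement disorders. Clinical motion-capture laboratories record full-body
3D marker trajectories (120 Hz, positions in mm) during standardized
tasks, and clinicians annotate each of 16 body extremities as *tremor
present* or *tremor absent*. `tremorkit` implements, tests and compares
six processing pipelines that automate that judgment from the kinematic
data alone. It is aimed at movement-analysis engineers and clinician
researchers who maintain or evaluate tremor detection pipelines.

## The pipelines

All six share a spectral premise: pathological tremor is a narrowband
4–12 Hz oscillation, voluntary movement concentrates below 2–3 Hz, and
marker jitter dominates high frequencies.

| id | kinematic domain | features | classifier |
|-----|------------------|----------|------------|
| A1r | velocity | engineered spectral-peak descriptors, winner-take-all across markers | fixed rules |
| A1s | velocity | same | SVM (RBF) |
| A2r | displacement | dominant peak of max-aggregated amplitude spectra | fixed rules |
| A2s | displacement | same | SVM (RBF) |
| B1 | position magnitude | 61-point smoothed Welch PSD (0–20 Hz) | SVM |
| B2 | position magnitude | same | XGBoost |

**A1** low-pass-filters each marker trajectory (zero-phase, 20 Hz),
differentiates with a Savitzky–Golay derivative filter, estimates per-axis
Welch PSDs combined by the Euclidean norm
`p(f) = sqrt(Px² + Py² + Pz²)`, and extracts the in-band maximum with its
3 dB borders. A peak is called tremor when it is narrow
(`BW = HI_F − LO_F ≤ 2 Hz`), symmetric (border powers within 3 dB) and
centred at `F_CENTER ≤ 10 Hz`; the marker with the largest
sinusoid-equivalent velocity amplitude `sqrt(2 · P_peak · ENBW)`
represents the extremity.

**A2** high-pass-filters displacement (zero-phase Butterworth, 2 Hz),
takes single-sided FFT amplitude spectra of every axis of every marker,
aggregates them by elementwise maximum, smooths, and finds the dominant
local peak. Tremor is present when `3.5 Hz ≤ F_CENTER ≤ 10 Hz` and
`AMPLITUDE_MM ≥ 0.1 mm`.

**B** reduces each marker to its distance from the kinematic origin
`r(t) = sqrt(x² + y² + z²)`, band-passes 1–20 Hz (order-80 Hamming FIR,
group-delay compensated), decimates 120 → 40 Hz, estimates a Welch PSD
(120-sample Hamming windows advanced by 10 samples, i.e. 3 s windows with
2.75 s overlap, 0.33 Hz bins), smooths with a 1 Hz Gaussian kernel, and
keeps the 61 one-sided values (DC–20 Hz) averaged across markers as the
classifier input.

Evaluation uses stratified 5-fold cross-validation with accuracy,
precision, recall, specificity and F1 from the confusion counts, plus
ROC/PRC curves with AUROC/AUPRC for the score-producing pipelines.

Because clinical recordings are not redistributable, the package includes
a seeded synthetic motion-capture simulator (`simulate_dataset()`,
`simulate_recording()`) that reproduces the spectral structure above, so
every stage — file I/O to cross-validated classification — runs and is
tested without any data download.

## Worked example

```r
library(tremorkit)

ds <- simulate_dataset(60, prevalence = 0.3, seed = 42)
ds
#> <tremor_dataset> 60 recordings (18 present / 42 absent), seed 42

ds$recordings[[1]]
#> <extremity_recording> Shoulders, trial sim0001
#>   815 frames at 120 Hz (6.79 s), 3 marker(s): Shoulders.M1, Shoulders.M2, Shoulders.M3
#>   label: present

fit <- tremor_fit(ds, "a2r")        # rule pipeline: no training involved
table(truth = ds$labels, predicted = predict(fit, ds))
#>          predicted
#> truth     absent present
#>   absent      42       0
#>   present      4      14

cross_validate(ds, "b2", k = 5, seed = 1)
#> <tremor_cv> pipeline B2, 5-fold stratified CV (seed 1)
#>   f1           0.881 (0.115)
#>   accuracy     0.934 (0.066)
#>   precision    0.950 (0.112)
#>   recall       0.833 (0.156)
#>   specificity  0.978 (0.050)
#>   auroc        0.994 (0.012)
#>   auprc        0.990 (0.022)
```

The A2r confusion table shows the rule detector recovering 14 of 18
tremor-present recordings with no false positives — its misses here are
faint tremors near the 0.1 mm amplitude rule. The `tremor_cv` summary
reports each metric as mean (sd) across the five held-out folds; at this
small n the fold-to-fold spread is still wide. On the package's standard
benchmark (`tremor_benchmark()`, n = 400) every pipeline reaches F1 ≥ 0.9.

A command-line interface wraps the same functions for shell use:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tremorkit.R", package = "tremorkit"))')" \
  simulate --n 100 --prevalence 0.32 --seed 7 --out data/
```

with subcommands `simulate`, `extract`, `detect` and `evaluate`.

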