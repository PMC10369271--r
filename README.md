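# pdglove

Quantitative hand-function assessment for Parkinson's disease from a
multimodal sensor glove: finger-flexibility grading from bend sensors,
muscle-strength grading from pressure sensors, and tremor-severity
classification from a triaxial accelerometer — plus the agreement
statistics (Cohen's kappa with Z-score, ICC) used to compare the system's
grades with a clinician's.  Everything runs on synthetic recordings, so
the whole pipeline is usable and testable without glove hardware.

The package is aimed at researchers in wearable movement analysis and
digital health who need a transparent, reproducible reference
implementation of this assessment pipeline.

## The methods at its core

* **Signal conditioning** — exponentially weighted average
  (`y[t] = αx[t] + (1−α)y[t−1]`) for slow bend/pressure channels; for
  accelerometry a median filter (window 5), a zero-phase 4th-order
  Butterworth bandpass at 3–8 Hz (the rest-tremor band; 100 Hz sampling,
  ±4 g range), and an adaptive scalar Kalman filter whose noise variances
  are re-estimated from a trailing innovation window.
* **Flexibility (F0–F4)** — bend angles min–max normalised from
  [0°, 180°] to [0, 1]; the grade is the bin of the maximum normalised
  bend over the nine assessment gestures, refining the TAM
  range-of-motion standard.
* **Strength (M0–M5)** — a from-scratch one-dimensional K-means
  (assign to nearest centre `c(i) = argmin_j ‖x(i) − μ(j)‖²`, update
  `μ(j) = Σ_{x∈c(j)} x / n_j`, k = 6) partitions population force maxima
  into six intervals mapped onto the Lovett scale; a subject's grade is
  the interval of their maximum force over four grip/pinch actions.
* **Tremor (No/Mild/Severe)** — axes fused into the combined acceleration
  `a(k) = √(ax(k)² + ay(k)² + az(k)²)`; nine features (peak-to-peak, SD,
  RMS, their logs, and three per-axis dominant frequencies in 3–8 Hz)
  feed a from-scratch 9-6-3 back-propagation network (sigmoid hidden
  layer, softmax output, cross-entropy), selected by stratified ten-fold
  cross-validation and evaluated with confusion-matrix metrics and
  one-vs-rest AUC.
* **Agreement** — Cohen's κ = (p₀ − pₑ)/(1 − pₑ) with the large-sample
  null-variance Z-score, and single-measurement ICC (two-way mixed,
  absolute agreement, i.e. ICC(A,1)) with McGraw–Wong 95% confidence
  intervals.

See `vignettes/glove-assessment-methods.Rmd` for the full methodological
account.

## Worked example

Simulate a severe-tremor recording, extract its feature vector, train the
classifier on a 120-sample synthetic dataset and evaluate on a held-out
stratified 20% split:

```r
library(pdglove)

rec <- simulate_tremor(severity = 2, seed = 11, freq = 5, amplitude = 0.8)
rec
#> <recording> kind=accel  500 samples x 3 channels  fs=100 Hz  [g]
#>   meta: label=2, freq=5, amplitude=0.8, seed=11

round(extract_features(rec), 3)
#>     p2p log_p2p      sd  log_sd     rms log_rms  freq_x  freq_y  freq_z
#>   0.589  -0.530   0.136  -1.996   0.646  -0.437   5.000   5.000   5.000

ds   <- simulate_dataset(120, seed = 1)          # 40 per severity class
fold <- stratified_folds(ds$labels, 5, seed = 1) # fold 1 = the 20% test set
fit  <- bpnn_train(ds$features[fold != 1, ], ds$labels[fold != 1], seed = 1)
evaluate(fit, ds$features[fold == 1, ], ds$labels[fold == 1])
#> <eval_report> accuracy 95.83% (n = 24)
#>               precision  recall      F1   AUC
#> No tremor       100.00% 100.00% 100.00% 1.000
#> Mild tremor      88.89% 100.00%  94.12% 0.961
#> Severe tremor   100.00%  87.50%  93.33% 0.984
```

The feature vector reads: the fused tremor has a 0.59 g peak-to-peak
swing, 0.65 g RMS (large — a severe tremor), and all three axes oscillate
at the injected 5 Hz.  On the held-out set the network misses one of 24
recordings.

Agreement between the classifier and the reference labels on a 24-sample
test set, as a rater table:

```r
cohen_kappa(matrix(c(8, 0, 0,
                     0, 9, 1,
                     0, 0, 6), 3, byrow = TRUE))
#> <kappa> 0.937 (excellent)  Z = 6.473  p = 9.602e-11  n = 24
```

A shell entry point wrapping the same functions is installed as
`exec/pdglove` (subcommands `simulate`, `extract-features`, `train`,
`evaluate`, `assess-flexibility`, `assess-strength`, `run-assessment`,
`agreement-kappa`, `agreement-icc`, …).

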