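# crackler

Automated detection of respiratory crackles in lung-sound recordings by
time-varying autoregressive (TVAR) modeling.

Crackles are discontinuous adventitious lung sounds: broadband transients
shorter than ~20 ms superimposed on the basal breath sound. Their presence
and their timing within the respiratory cycle carry diagnostic information
(e.g., fine inspiratory crackles in restrictive interstitial disease), but
they are easy to miss by ear. `crackler` implements a detector for
maneuver-guided recordings (10 kHz, mono, 16-bit WAV), together with a
fully synthetic evaluation bench: parametric crackle waveforms, a surrogate
basal-sound generator, six phase-targeted insertion scenarios with exact
ground truth, and sensitivity/specificity scoring with ROC-based threshold
selection. It is aimed at researchers in respiratory sound analysis who
need a reproducible, tested reference implementation of this detector
family.

## The model

The preprocessed signal (mean removal, 500th-order FIR bandpass 75–1000 Hz,
peak normalization to [−1, 1]) is modeled as a time-varying autoregression

    s_FN[n] = − Σ_{k=1..M} a_k[n] · s_FN[n−k] + v[n],    M = 4,

whose coefficients are re-estimated at every sample by exponentially
weighted recursive least squares (forgetting factor λ = 0.97, cost
ξ[n] = Σ_i λ^{n−i} |e[i]|²). A crackle is a local model violation: it makes
the coefficient trajectories a_k[n] jump. The detector takes the first
difference of each coefficient series, splits the derivatives into
consecutive 4 ms windows, and in every window where the standard deviations
of **all four** derivative series exceed a threshold (default thr = 0.024)
it sums the absolute derivatives, locates the in-window maximum, and emits
that time index as a crackle onset if the summed series' slope turns from
positive to negative there. Detected onsets are phase-labeled against the
guided breathing maneuver (2 s apnea, four 4 s cycles at I:E = 2:3, 2 s
apnea).

Synthetic crackles follow the classical two-parameter model
x(t) = sin²(πt) · sin(4π t^γ) with γ = log 0.25 / log(IDW/2CD) on
normalized time, so the first carrier zero falls at the initial deflection
width (IDW) and the waveform spans exactly two cycles over its duration
(2CD). Presets: fine = 0.5/5 ms, coarse = 1.2/9 ms. Inserted crackles are
scaled so their variance over their support is `gain` × the local basal
variance (gain ∈ {1.5, 2.5, 3.5}).

Performance uses Acc = TP/(TP+FN+FP), Sen = TP/(TP+FN), Spe = TN/(TN+FP),
with detections matched to insertions within 3 samples and true negatives
counted over the detector's 4 ms windows.

## Worked example

```r
library(crackler)

sc  <- simulate_scenario(1, gain = 3.5, seed = 7)   # 10 fine crackles per inspiration
det <- detect_crackles(sc$recording, maneuver = maneuver_template())
det
#> Crackle detection: 40 event(s) in 20.00 s (thr = 0.024, 4 ms windows, TVAR(4), lambda = 0.97)
#>    onset_sample onset_s       phase cycle
#> 1         20836  2.0835 inspiration     1
#> 2         21139  2.1138 inspiration     1
#> ...

cc <- match_events(sc, det)
cc
#> TP 39  FN 1  FP 1  TN 4957 (tolerance 3 samples, 5000 windows)
performance_metrics(cc)
#> Acc 95.12%  Sen 97.50%  Spe 99.98%  mean|dt| 0.22 ms  median|dt| 2.00 samples
```

39 of the 40 inserted crackles are recovered within 3 samples of their
insertion point (one missed, one extra detection); specificity is computed
over the 5000 analysis windows of the 20 s recording. `summary(det)` prints
the per-cycle, per-phase count table.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/crackler.R simulate --scenario 1 --gain 3.5 --seed 7 --outdir out/
Rscript inst/cli/crackler.R detect   --input out/scenario1_gain3.5_seed7.wav --output det.txt
Rscript inst/cli/crackler.R sweep    --scenarios 1,5 --gain 3.5 --seeds 1,2 --output sweep.csv
```

## Layout

- `R/`, `src/` — package code (RLS inner loop in C++ via Rcpp)
- `tests/testthat/` — unit, property, and end-to-end acceptance tests
- `vignettes/crackle-detection.Rmd` — methods notes: model, parameter
  choices, surrogate design, numerical conventions, limitations
- `inst/cli/crackler.R` — command-line front end
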