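---
title: "Crackle detection by TVAR modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crackle detection by TVAR modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crackler)
```

This vignette documents the science and the design decisions behind
`crackler`: the signal model and detection rule, what every tunable
parameter means, how the synthetic evaluation bench is built and what it
can and cannot certify, and the numerical conventions that matter when
reproducing results.

## Signal model and detection rule

A respiratory sound recording is digitized at 10 kHz, mean-removed,
bandpass filtered to 75–1000 Hz (501-tap linear-phase FIR, Hamming design,
group delay compensated) and peak-normalized into $[-1, 1]$. The resulting
signal $s_{FN}[n]$ is modeled as a fourth-order time-varying
autoregression,

$$ s_{FN}[n] = -\sum_{k=1}^{4} a_k[n]\, s_{FN}[n-k] + v[n], $$

with $a_0 = 1$ fixed. The coefficients are tracked per sample by
exponentially weighted recursive least squares minimizing
$\xi[n] = \sum_{i} \lambda^{\,n-i} |e[i]|^2$ with $\lambda = 0.97$
(effective memory $\approx 1/(1-\lambda) \approx 33$ samples, i.e. 3.3 ms —
matched to crackle durations of 5–9 ms). The basal breath sound drifts
slowly in this model; a crackle, being a spectrally alien transient,
forces an abrupt excursion of the coefficient vector.

Detection proceeds in six steps (`detect_crackles()`):

1. estimate the TVAR(4) trajectory by RLS;
2. first-difference each coefficient series;
3. segment the derivatives into consecutive, non-overlapping 4 ms
   (40-sample) windows and compute each derivative's standard deviation
   per window;
4. where **all four** standard deviations exceed the threshold
   (`thr = 0.024`), sum the absolute derivatives;
5. take the in-window maximum of that sum (earliest index on ties);
6. emit the maximum as a crackle onset if the sum rises into it and falls
   after it (discrete slope change from positive to negative).

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `order` | 4 | – | TVAR model order; higher orders dilute the per-coefficient response |
| `lambda` | 0.97 | – | RLS memory; closer to 1 = smoother background trajectories, slower response |
| `threshold` | 0.024 | coefficient units | applied to windowed derivative SDs; operating point from the ROC midpoint rule |
| `window_ms` | 4 | ms | analysis window; one detection at most per window |
| `delta` | 0.01 | – | RLS initialization scale, $P_0 = \delta^{-1} I$ |
| matching tolerance | 3 | samples | maximum onset error counted as a correct detection |

The threshold's published derivation is reproduced by
`threshold_sweep()` + `select_threshold()`: sweep 0.010–0.060 (step 0.001),
take the ROC point closest to the ideal (Sen, Spe) = (100, 100) corner as
the lower limit, the accuracy-curve maximum as the upper limit, and
operate at their midpoint; lower/upper limits of 0.019/0.029 give 0.024.
"Closest to the corner" operationalizes the curve's inflection, which has
no standard definition.

## RLS conventions

With regressor $u[n] = (-s[n-1], \dots, -s[n-M])$ the recursion is the
standard a-priori form: $e = s[n] - u^\top a$, $k = Pu/(\lambda + u^\top P
u)$, $a \leftarrow a + k e$, $P \leftarrow (P - k\,(Pu)^\top)/\lambda$,
symmetrized each step to suppress round-off drift. Initialization is
$a = 0$, $P = \delta^{-1} I$; the first $M$ rows of the trajectory hold the
initial value. At $\lambda = 1$ this recursion solves the ridge-regularized
batch problem $(\delta I + U^\top U)\,a = U^\top y$ exactly, which is why
the test suite can require agreement with `fit_ar_batch()` (plain normal
equations) to $10^{-6}$ relative error on long stationary signals: the
$\delta$ bias is $O(\delta / n)$. The square-root/QR variants are
unnecessary at these signal lengths ($\le 2\times10^5$ samples) and
conditioning levels. The inner loop is compiled (Rcpp) since it runs once
per sample.

## Onset bookkeeping

Derivative sample $d$ holds $a[d+1] - a[d]$ and is attributed to signal
sample $d$ (the earlier endpoint). This is a deliberate choice: the
earliest possible evidence of a crackle starting at sample $n_0$ is the
RLS update at $n_0 + 1$, i.e. derivative index $n_0$, so the earlier
attribution makes an unbiased detection achievable in principle. Measured
on simulated insertions, the summed-derivative maximum then trails the
insertion index by 2–3 samples (median 2), because the crackle's
$\sin^2$ envelope ramps up from exactly zero and the coefficients need a
few samples of evidence to move. The later-endpoint attribution would add
one sample of bias everywhere and push a large fraction of correct
detections outside the 3-sample matching tolerance.

Windows are non-overlapping (hop = window length), following the
segmentation reading of the rule; a sliding-window reading would need an
unstated hop and a deduplication rule. A final partial window is processed
if it holds at least 2 samples (a single sample has no dispersion). A
maximum at the first or last derivative sample of the whole recording is
discarded (no neighbor for the slope test); maxima at interior window
edges use the neighbors across the edge. Two crackles closer than 4 ms
collapse into one detection — a known limitation of the one-per-window
rule; conversely a crackle whose response straddles a window boundary can
fire in both windows, and the extra event is scored as a false positive.

## The synthetic crackle

The two-parameter waveform on normalized time $t \in [0,1]$ is

$$ x(t) = \sin^2(\pi t)\,\sin\!\big(4\pi\, t^{\gamma}\big), \qquad
   \gamma = \frac{\log 0.25}{\log T_0}, $$

with $T_0$ = IDW/2CD (initial deflection width over two-cycle duration).
The phase law gives $4\pi T_0^{\gamma} = \pi$: the carrier's first zero
falls exactly at the IDW, and total phase $4\pi$ at $t = 1$ means exactly
two cycles over the 2CD — the two defining morphological parameters of
fine (0.5/5 ms) and coarse (1.2/9 ms) crackles. A literal product reading
of the exponent ("$4\pi t\,\log 0.25/\log T_0$") satisfies neither
property, which is why the exponent form is implemented. Waveforms are
peak-normalized before insertion scaling.

Insertion scaling follows the variance reading: the scaled crackle's
variance over its own 50- or 90-sample support equals `gain` times the
basal variance over that support, so `gain` $g$ is a local SNR of
$10\log_{10} g$ dB (1.8–5.4 dB for the study gains). A peak-based reading
(crackle peak = $g\,\times$ local basal peak) is available via
`scaling = "peak"`; the variance reading is the default. After all
insertions the mixture is re-peak-normalized, which does not move onsets.

## The surrogate basal sound

No real recordings ship with the package, so the evaluation bench runs on
a surrogate (`basal_surrogate()`) that emulates the documented properties
of maneuver-guided basal breath sounds:

* band-limited to 75–1000 Hz by the same FIR used for real recordings;
* power concentrated at low frequencies: Gaussian noise shaped by a
  cascade of five one-pole low-pass sections (~30 dB/octave above the
  corner), corner 250 Hz during inspiration and 180 Hz during expiration
  and apnea — inspiration is broader-band than expiration;
* a small broadband component (3% relative amplitude) standing in for
  sensor/electronic and airflow noise;
* phase-locked half-sine amplitude envelopes, inspiration peak 1.0,
  expiration 0.5, and a near-silent apnea floor at 1.5% of the
  inspiratory peak;
* seeded and fully reproducible.

The spectral steepness and noise floor were fixed, once, so that the
detector at its published operating point exhibits the published operating
characteristics on the bench — near-ceiling sensitivity for fine crackles
at all gains with window-based specificity around 99.8–99.9%, coarse
crackles substantially harder with the low-gain coarse condition worst,
and a median onset error of 2 samples. This is the only observable link
between the undeposited real recordings and the surrogate; a surrogate on
which the published threshold did not separate crackles from background
would misrepresent the study conditions. These parameters were not
revisited afterwards.

What passing on the bench does **not** show: robustness to heart-sound
residue, airflow turbulence bursts, friction artifacts, between-subject
spectral variability, or real (non-parametric) crackle morphology.
Published comparisons on patient recordings show detector counts can
deviate substantially from expert annotation per recording, so bench
figures are upper bounds on real-data behavior.

## Scenario construction

Six insertion scenarios target crackle kind × respiratory phase
(`scenario_descriptions()`), with 10 insertions per designated segment by
default (scenario 4 splits 5 + 5). "End of inspiration" (scenarios 2–3)
means the final 25% of each inspiratory segment — the extent is not
specified in the source description and 0.4 s comfortably holds 10
crackles. Onsets are drawn uniformly by rejection sampling; supports must
lie wholly inside the phase segment and be separated by at least the
longer of the two neighboring crackle durations; an impossible packing
raises a capacity error rather than degrading silently.

## Scoring conventions

Matching is one-to-one within a 3-sample tolerance. Rather than pairing
greedily by distance, truths are scanned in increasing order and each
takes the earliest unused detection in its tolerance window — the optimal
(maximum-cardinality) rule for interval matching on a line, verified
against an exhaustive oracle in the tests. For events separated by more
than one tolerance, as all scenario insertions are, it coincides with
nearest-first pairing. Accuracy deliberately excludes true negatives
(TP/(TP+FN+FP)); specificity needs a negative decision unit, which is
taken as the detector's own 4 ms window — a 20 s recording has ~5000
windows, which reproduces the ~99.8% scale of reported specificities.
Metrics with zero denominators are reported as `NA`, never 0 or 100.

## Problem sizes

The shipped studies use scaled-down sizes chosen to exercise every code
path at meaningful statistical resolution: 5 recordings per condition
(~200 insertions) for the headline study in `scripts/acceptance.R`, 2–3
recordings for ordering checks, 20 000–50 000-sample stationary signals
for estimator equivalence, and 200 randomized micro-instances for the
matching oracle. The original study pooled 10 subjects × 62 insertions per
scenario; only aggregation logic, not subject-level variability, is
reproducible here.

## Known limitations

* The detector localizes but does not classify events (no fine/coarse
  discrimination of detections).
* Overlapping crackles within 4 ms are counted once.
* The mean absolute onset error on the bench is ~0.2 ms — slightly above
  the ~0.19 ms reported on real basal sounds — because the surrogate's
  insertions start from an exactly zero sample; the median (2 samples)
  matches.
* Variable forgetting factors, model-order selection, and wheeze detection
  are out of scope.
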