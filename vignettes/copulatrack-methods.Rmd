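---
title: "Methods: copula-based tracking of speech features in neural time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copula-based tracking of speech features in neural time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copulatrack)
```

## Overview

`copulatrack` measures the statistical dependence ("tracking") between
slow stimulus features of continuous speech and band-limited neural
activity, separates redundant from genuine cross-modal tracking with
conditional mutual information, tests the results with surrogate-based
maximum-statistic inference, and relates tracking strength to
word-recognition behavior. This vignette documents the model assumptions,
the tunable parameters, the synthetic cohort the test suite runs on, and
the numerical and design choices a maintainer should know about.

## Signal model and feature representation

Six stimulus features at 50 Hz form two groups of equal dimensionality:
acoustic (`aud_env`, `aud_slope`, `aud_pitch`) and lip (`lip_area`,
`lip_slope`, `lip_width`). The broadband envelope is the mean of 12
band-limited Hilbert envelopes (zero-phase third-order Butterworth bands
logarithmically spaced from 0.1 to 10 kHz); slopes are exact first
differences with a leading zero so all features stay time-aligned; the
pitch contour comes from a frame-wise autocorrelation F0 tracker (40-ms
frames, 60–300 Hz search range). Unvoiced frames are flagged and linearly
interpolated before any information-theoretic step, because the estimator
needs a complete series; the flags are kept in the output so downstream
users can weigh that choice.

Per trial, the first 500 ms are discarded (onset transient), trials are
concatenated along time, the record is band-passed (zero-phase third-order
Butterworth; canonical bands 0.5–1, 1–3, 2–4, 3–6, 4–8, 0.5–8 Hz), and
the Hilbert analytic signal is taken over the whole concatenated record.
We follow the stated order — concatenate, then filter, then transform —
and accept the boundary transients this implies; forward–backward
filtering uses odd-reflection padding of about three time constants of the
band's lower edge to keep those transients small on short records.

## The estimator

Every variable enters as a (real, imaginary) pair of its analytic signal,
so a single feature contributes two dimensions and a three-feature group
six. Each dimension is rank-normalized: ranks (ties broken by order of
appearance, hence deterministic) mapped through the standard-normal
quantile at rank/(n+1). MI and CMI are then computed from Gaussian
entropies of the transformed blocks, each entropy corrected by the exact
Wishart expectation of the log-determinant (digamma terms), which makes
the entropy estimator unbiased for Gaussian data at any n. Covariances use
the 1/(n−1) convention; a joint covariance with condition number above
1e12 raises an error naming the collinear dimensions.

Two consequences of the copula are worth stating. First, estimates are
invariant under any dimension-wise strictly monotone transform of the
inputs — which is why the generator's soft-rectification of features is
harmless. Second, the estimator captures dependence through the Gaussian
copula only; at very high SNR, near-deterministic nonlinear relations
saturate it slightly below the true MI. The test suite pins the estimator
to closed forms (bivariate Gaussian MI at ρ = 0.8; trivariate partial
correlation 0.5) and to a histogram plug-in oracle on dependent data.

## Bias matching, baselines, and lags

Raw MI and CMI have different small-sample biases, so their comparison
uses a bias-matched MI: the mean over repeated random circular time
shifts of `I(X; Y | X_shifted)`. The shift is drawn uniformly outside a
±2 s guard (`t_min`), chosen to exceed the autocorrelation range of the
slowest band (0.5 Hz), and it is applied to the whole stimulus block
jointly so the features' mutual alignment is preserved. Baseline
subtraction — the mean of the same estimator over 100 surrogate shifts —
recenters all reported values on the zero-MI expectation. Defaults are
2000 bias-matching repetitions, 100 baseline and 2000 max-null surrogates,
and 5000 label permutations; `run_config(test_mode = TRUE)` switches to
50/20/200/500 for desk-scale runs, and the tests document correspondingly
widened tolerances.

Stimulus-to-brain lags are searched on a 0–500 ms grid in 20-ms steps
(one sample at 50 Hz per step). Both lags and surrogate shifts are
implemented as circular shifts of the concatenated record; a surrogate
shift s at lag l is therefore the same computation as a lag of l+s, which
the cohort-level code exploits so that a full surrogate ensemble costs
little more than one estimate. The group-level optimal lag maximizes the
median across participants of the condition-summed profile (the
aggregator is not dictated by the analysis convention we follow; the
median matches the group statistics used elsewhere), with ties broken
toward the smaller lag, and final values average the seven estimates in a
±60 ms window around the optimum, clipped at the grid edges with the
number of in-range lags recorded.

One finding from validating the lag search deserves emphasis: when a
feature group contains the exact first difference of another member (as
`aud_slope` does of `aud_env`), the pair (x, dx) acts as a short backward
window on x, and in a narrow band the analytic representation extrapolates
the past better than the future. The population lag profile then flattens
and peaks one to two grid steps early even for a perfectly planted delay.
This is a property of the estimator definition, not an implementation
artifact (a minimal reproduction with X = (x) recovers the planted lag
exactly; adding dx shifts the peak). In the broad 0.5–8 Hz band the
profile is sharp and recovery is exact, so the lag-recovery benchmark runs
there; per-band optimal lags remain what they are — band-specific
empirical quantities. Users interpreting narrow-band optimal lags should
expect this lead bias.

Lag selection always happens on the plain MI profile; conditional values
are then evaluated at the selected lag. Selecting on the CMI itself would,
under the null, prefer lags at which the conditioner is misaligned and so
manufacture leakage.

## Inference

Per band, surrogate MI values are pooled across participants, conditions,
ROIs and feature groups; the largest 2000 are kept and their 99th
percentile is the corrected threshold for the group-level median
(one-sided, α = 0.01, strict inequality). Observed statistics are compared
with this null on the same (un-subtracted) scale; baseline-subtracted
values are reported alongside for effect-size interpretation — subtracting
a common constant from both sides would not change any decision. When the
pool is smaller than 2000 (reduced-repetition runs) all values are used
and a warning is raised. Randomization p-values are reported as
(r+1)/(n+1) and are never exactly zero. MI-vs-CMI contrasts use the exact
Wilcoxon signed-rank z (tie-corrected, continuity-corrected) with a
max-|z| permutation null over the whole correction scope; the choice of
|z| rather than signed z is configurable. Feature-wise and area-wise
comparisons use Kruskal–Wallis with ε² = χ²/(n−1) (the standard rank
epsilon-squared; no formula is dictated by the convention we follow) and
Tukey–Kramer on mean ranks with the harmonic-mean correction; FDR control
is Benjamini–Hochberg within each table.

## Brain–behavior link

Percent-correct scores (four-choice task, chance 0.25) in the visual
condition are regressed on the z-scored tracking values of interest
(envelope tracking in temporal channels, pitch tracking in occipital
channels) together with two confounds that proxy each participant's
overall SNR: lip-feature tracking in occipital channels (visual trials)
and acoustic-feature tracking in temporal channels (auditory trials),
each z-scored per band and averaged across bands. One model is fit per
band; bands are never pooled in a single fit. The Bayes factor between
the full and the target-free model is exp(ΔBIC/2) — the standard BIC
approximation, with BF > 1 favoring the full model — and partial
residuals follow the Velleman–Welsch construction, whose slope against
the target equals the model coefficient exactly (an identity the tests
check to 1e-10).

## The synthetic cohort

The generator emulates the study conditions: 18 participants, 180
sentence-trials of duration Normal(5.4, 0.4) s truncated to [4.6, 6.5] s,
features at 50 Hz. Features are band-limited (< 10 Hz) Gaussian processes
with 1/f-shaped spectra; the envelope and lip area share a latent
component whose mixing weight is solved analytically from the coherence
target (weight² = √coherence, giving coherence = weight⁴ at equal
spectra), so the default target of 0.2 lands within ±0.05 when measured
with the package's own Welch procedure over a full cohort. Nonnegative
features are produced by offsetting three standard deviations and
soft-rectifying (softplus), which is nearly the identity there and,
because the estimator is rank-based, statistically inert. Pitch and lip
width share the latent weakly (weights 0.1 and 0.3) for realism.

Neural channels are gain-weighted sums of integer-sample-delayed
standardized features (lags on the 20-ms grid, drawn per participant from
60–140 ms) plus 1/f noise, scaled so the signal/noise variance ratio
equals `snr`. In audio trials the temporal channels carry the acoustic
drive; in visual trials the occipital channels carry the lip drive plus
`leak` times the acoustic drive, and temporal channels the leaked acoustic
drive alone — `leak` is a modelling stand-in for whatever mechanism
produces restoration, not a claim about that mechanism. Because of the
SNR normalization, `leak` controls the acoustic *share* of a visual
channel rather than its total signal power; a planted gain increase at
fixed noise corresponds to snr = gain². Behavioral scores are
base + 0.1·(β·z(gain) + √(1−β²)·ε), clipped to [0.25, 1], with bases 0.70
(audio) and 0.71 (visual); the unit-variance construction means a
standardized regression on the z-scored planted gain recovers β directly.
One global seed expands into per-participant and per-trial child seeds
through a counter scheme, so any participant can be regenerated alone and
the whole cohort is bit-reproducible.

What the generator does not emulate: articulator dynamics, MEG forward
physics, heteroscedastic or non-stationary noise, eye movements, and any
nonlinear neural transform of the features. Passing tests therefore
demonstrate that the pipeline recovers planted structure of this linear,
stationary kind — not that real recordings contain such structure.

## Validation studies and their sizes

The test suite runs, at fixed seeds: estimator recovery at n = 10,000
(12 replicates); bias-matching on 200 independent cohorts of 2000 samples
(10 shifts each); family-wise calibration on 200 global-null cohorts of
18 participants × 60 trials (one 1–3 Hz band, visual condition, 2 ROIs ×
2 feature groups, one channel per ROI, 12 surrogates per cell — pooled
max-null as in the full pipeline); lag recovery over 20 cohorts
(8 participants × 30 trials, snr 6, 0.5–8 Hz) with planted lags 60/100/140
ms; restoration detection over 10 cohorts per leak level (12 participants
× 40 trials, snr 4, leak 0 vs 0.6, 15 surrogates per participant); and
behavior recovery over 500 (coefficient) and 2000 (type-I) simulated
cohorts of 18 participants. `scripts/acceptance.R` re-runs the same
studies from a command-line seed.

## Numerical choices

* Fourier transforms of arbitrary-length records go through a Bluestein
  chirp-z fallback when the length has a large prime factor; R's
  mixed-radix FFT is used otherwise. Shaped-noise generation pads to a
  2-3-5-smooth length and truncates.
* Resampling (audio envelope to 50 Hz, lip series 25 → 50 Hz) uses a
  zero-phase anti-alias low-pass at 0.8 × the target Nyquist followed by
  linear interpolation; lip slope is computed at the native 25 fps before
  interpolation, mirroring the stated processing order.
* Copula ties break by order of appearance; constant dimensions raise an
  error rather than silently degenerate.
* The on-disk cohort container is plain text (per-trial TSV plus JSON
  sidecars at full double precision) and round-trips losslessly.

## Known limitations

* The Gaussian-copula estimator bounds dependence through the copula; it
  under-reports strongly nonlinear or high-SNR deterministic coupling.
* Narrow-band optimal lags inherit the derivative-feature lead bias
  described above.
* With heterogeneous per-participant lags, conditioning at a single
  group-level lag partials the conditioner slightly imperfectly; the
  max-statistic threshold absorbs the small residual in all regimes we
  tested, but the residual exists.
* The permutation Wilcoxon uses the normal approximation for z (adequate
  at n = 18); an exact-distribution option exists for small samples.
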