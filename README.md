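# copulatrack

Quantifying how neural time series track the features of continuous speech —
heard or unheard — with Gaussian-copula mutual information.

## The problem

When a listener follows connected speech, low-frequency (≲ 8 Hz) cortical
activity tracks slow acoustic features: the amplitude envelope, its rate of
change, and the pitch (F0) contour. During silent lip reading the same
machinery appears to *restore* acoustic features that are physically absent,
guided by the visible lip movements. Demonstrating restoration is
statistically delicate: lip aperture and the acoustic envelope are mutually
coherent (magnitude-squared coherence ≈ 0.2 in the 1–3 Hz band), so apparent
tracking of an unheard feature may be nothing more than tracking of the
visible one. The analysis this package implements answers that with
*conditional* mutual information: tracking of acoustic features given the
lip features, so that only the non-redundant part counts.

## The statistic

For a feature block X, a neural signal Y and a conditioning block Z — each
represented as the complex analytic signal of a band-limited series, split
into (real, imaginary) pairs — the package estimates, in bits,

- MI: `I(X;Y) = H(X) + H(Y) − H(X,Y)`
- CMI: `I(X;Y|Z) = H(X,Z) + H(Y,Z) − H(X,Y,Z) − H(Z)`

where each entropy is a Gaussian entropy of rank-normalized (Gaussian
copula) data with an analytic small-sample bias correction (digamma
correction of `E[log det S]`). Because MI and CMI carry different estimator
bias, MI is additionally computed *bias-matched*:

`MI(X;Y) ≅ mean over shifts of I(X ; Y | X_shifted)`

with X_shifted a circularly time-shifted copy of X — an irrelevant
conditioner of the same dimensionality. All estimates are referenced to a
surrogate null (circular time shifts ≥ 2 s) and tested against a
maximum-statistic null distribution: per band, surrogate MI values are
pooled over participants, conditions, ROIs and feature groups, the largest
2000 retained, and the group-level median compared with their 99th
percentile (one-sided, corrected, α = 0.01). Group contrasts use a
label-permutation Wilcoxon signed-rank test with max-|z| correction,
Kruskal–Wallis omnibus tests with Tukey–Kramer post hocs, and
Benjamini–Hochberg FDR. Finally, word-recognition performance (percent
correct in a four-choice task) is regressed on z-scored tracking estimates
with SNR-proxy confounds, with BIC-based Bayes factors and Velleman–Welsch
partial residuals.

A seeded synthetic-cohort generator (`scenario_config()`,
`simulate_cohort()`) provides feature streams with controlled
envelope–lip coherence, pseudo-neural channels that track delayed features
over 1/f noise (with a cross-modal `leak` parameter planting a restoration
effect), and behavioral scores coupled to each participant's tracking gain
— so every stage is testable against known ground truth.

## Worked example

```r
library(copulatrack)

scen <- scenario_config(n_participants = 7, n_trials = 8,
                        leak = 0.5, snr = 2, seed = 21)
cfg <- run_config(scenario = scen, seed = 21)
cfg$reps <- list(bias_match = 4, baseline = 4, max_null = 6, label_perm = 200)
run <- run_tracking(cfg)

subset(run$stats_report$median_tests, kind == "mi" & condition == "A")
#>  band kind condition       roi feature_set     median threshold significant
#>   1-3   mi         A  temporal     AudFeat 1.32770246 0.1011276        TRUE
#>   1-3   mi         A  temporal     LipFeat 0.32590081 0.1011276        TRUE
#>   1-3   mi         A occipital     AudFeat 0.04782517 0.1011276       FALSE
#>   1-3   mi         A occipital     LipFeat 0.04161885 0.1011276       FALSE

subset(run$stats_report$median_tests,
       kind == "cmi" & condition == "V" & feature_set == "AudFeat")
#>  band kind condition       roi feature_set    median threshold significant
#>   1-3  cmi         V  temporal     AudFeat 1.0495350 0.1011276        TRUE
#>   1-3  cmi         V occipital     AudFeat 0.2553524 0.1011276        TRUE
```

In audio-only trials the temporal channels track the acoustic feature group
(`AudFeat`, median MI ≈ 1.33 bits, far above the corrected surrogate
threshold of ≈ 0.10 bits), and also show apparent `LipFeat` tracking
(≈ 0.33 bits) — the redundancy that conditional MI discounts. Undriven
occipital channels stay below threshold. Because this cohort was planted
with `leak = 0.5`, the visual-condition CMI of acoustic features given lip
features is significant in both ROIs — the restoration signature — and
`run$regression[["1-3"]]` reports the standardized coefficients linking
tracking to word recognition.

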