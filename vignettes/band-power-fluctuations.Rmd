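---
title: "Band-power fluctuations and seizure evolutions: models and methods"
author: "seizmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power fluctuations and seizure evolutions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, assumptions, parameter choices and
known limitations of the `seizmod` pipeline. It states no empirical
result that the package's test suite or `scripts/acceptance.R` does not
itself compute.

## The model in outline

The pipeline treats continuously recorded multichannel intracranial
EEG as a superposition of band-limited activity whose *power* is
modulated over timescales of minutes to days. The object of inference
is not the raw signal but the trajectory of spectral patterns: which
combinations of channels and frequency bands wax and wane together, on
which timescales, and whether the state of those fluctuations at
seizure onset explains how similar or dissimilar pairs of seizure
evolutions are.

Five stages, each a small model with its own assumptions:

1. **Band power.** Welch's method on 30 s epochs (3 s Hamming
   segments, no overlap, one-sided density scaling, band integration
   over `[lo, hi)`). Assumes local stationarity within 3 s segments
   only. The per-band log transform plus pooled z-scoring assumes
   log-power is the natural scale on which channels are comparable;
   the logistic squashing `S(x) = 1/(1+exp(-x))` maps z-scores into
   (0, 1) so the matrix is nonnegative, at the cost of compressing
   tails beyond ±2 SD. Rows are stacked band-major (all δ channels,
   then θ, ...), and the ordering is recorded in `rowData`.
2. **NMF.** A low-rank nonnegative model `X ≈ W H` interprets each
   column of W as a recurrent spectral pattern and each row of H as
   its expression over time. Rank selection balances reconstruction
   error (mean absolute deviation < 0.05 on the (0,1) scale of X)
   against component redundancy (the largest absolute Pearson
   correlation among W columns or H rows); among admissible ranks the
   least redundant wins, ties to the smaller rank. If no rank is
   admissible the smallest-error fit is returned flagged — rule
   coverage for degenerate inputs, not a recommended operating point.
3. **MEMD.** The coefficient series H is decomposed into mode-aligned
   multivariate IMFs by projecting onto quasi-uniform directions
   (Hammersley construction pushed through the Gaussian quantile map,
   then a seeded rotation), interpolating envelopes through projection
   extrema with natural cubic splines (two extrema mirror-extended at
   each end), and subtracting the direction-averaged envelope mean
   until a Rilling-style criterion holds. EMD-family methods assume
   only that the signal is a superposition of locally narrow-band
   oscillations; they do not assume stationarity or a basis.
4. **Hilbert spectral analysis.** Each IMF dimension's analytic signal
   yields instantaneous amplitude and frequency; squared amplitudes,
   averaged over the k dimensions, are accumulated into log-spaced
   frequency bins (48 per decade, cycles/day) over time. Binning
   partitions valid samples, so per-IMF energy is conserved exactly —
   a property the tests assert to 1e-9 relative.
5. **Distance regression.** Seizure dissimilarity (DTW over evolution
   trajectories, mean local cost along the optimal path) is regressed
   on per-IMF seizure distances plus residue and temporal distances,
   all standardized, using a nonnegativity-constrained LASSO.
   Nonnegativity encodes the prior that distances can only explain
   dissimilarity positively. The penalty is chosen by 10-fold CV over
   the fixed grid `10^seq(-3, 2, 0.05)` (101 values); within mean-MSE
   ties the largest penalty (sparsest model) wins. An unconstrained
   OLS refit on the selected predictors supplies coefficients, 95%
   t-based confidence intervals (standardized scale), and adjusted R².

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| epoch length | 30 | s | temporal resolution of all downstream series (2,880 epochs/day) |
| Welch segment | 3 | s | 0.33 Hz resolution; 10 segments per epoch averaged |
| band edges | δ1–4, θ4–8, α8–13, β13–30, γ30–80 | Hz | canonical iEEG bands; γ's upper edge requires fs > 160 Hz |
| log floor | 1e-12 | — | all-zero epochs must not produce -Inf |
| NMF rank range | 3–15 | — | smallest range that covers few-pattern subjects without overfitting T ≫ n matrices |
| error threshold | 0.05 | — | mean absolute deviation on the (0,1) scale of X |
| MU tolerance / cap | 1e-5 / 500 | — | relative objective change; MU tail convergence is sublinear, so exact-rank inputs plateau near 1e-3 mean deviation |
| MEMD directions | 64 | — | ≥ 2k for k ≤ 15; quasi-uniform coverage of the (k−1)-sphere |
| sift stopping | θ₁ 0.05, θ₂ 0.5, α 0.25, cap 30 | — | see below |
| edge mask | 3% | of T | discrete Hilbert transform start-edge transient reaches ~2.8% at the slowest resolvable cycles |
| spectral bins | 48 | per decade | one bin ≈ 4.9% in frequency; spacing of peak-frequency reporting |
| circadian band | 0.8–1.25 | days (peak period) | tolerance around 1 cycle/day; ties resolved by total marginal power |
| LASSO grid | 10⁻³…10², step 10^0.05 | — | 101 penalties; full-shrinkage at the top end for standardized data |
| CV folds | 10 | — | pairs shuffled by seed, contiguous fold blocks |
| permutations | 500 | iterations | plain strictly-greater percentage p-value; a `corrected` flag enables (b+1)/(n+1) |

## Numerical choices

* **Sift stopping.** Sifting stops when the envelope-mean to
  envelope-amplitude ratio is below θ₁ on at least 1−α of interior
  samples and below θ₂ on all of them; the 3% edges are excluded
  because mirror-extension artifacts dominate there. α = 0.25 with a
  hard cap of 30: against the noise floor of a finite (64-direction)
  mean envelope, demanding α = 0.05 forces ~20 sifts per mode, which
  both wastes time and *over-sifts* — measured on white noise it drags
  the adjacent-mode mean-period ratio from the canonical near-dyadic
  ~1.8 down to ~1.57. With the default, white-noise interior ratios
  fall in [1.65, 2.25] across seeds (asserted in the tests).
* **Degenerate inputs.** All-zero epochs are floored before the log;
  zero pooled SD within a band is an error (the matrix cannot be
  standardized); an all-zero marginal spectrum is an error; an
  all-zero IMF power row is an error; constant predictor columns are
  dropped with a warning; a constant response marks the regression
  dataset degenerate and every fit on it reports adjusted R² = 0.
* **Tie-breaks.** Spectral peak ties go to the lower frequency
  (logged); rank-selection redundancy ties to the smaller rank; CV-MSE
  ties to the larger penalty; DTW backtracking prefers the diagonal.
* **Empty LASSO selection** reports adjusted R² = 0 with no OLS stage
  and a flag. Under the permutation nulls this happens in roughly
  60% of iterations, which makes the null distribution of adjusted R²
  strongly discrete: the 5%-level rejection rate is calibrated
  (measured 4% over 100 null replicates in the acceptance suite), but
  the p-value *distribution* is far from uniform. Readers should use
  the tests as accept/reject procedures at the stated level, not as
  uniformly distributed p-values.
* **Onset epochs.** A seizure's epoch is `floor(onset_s / 30)`
  (0-based); `lag = 1` reproduces the pre-ictal sensitivity variant
  one epoch before onset. Random-times permutations draw epochs
  i.i.d. uniformly on {0, …, T−1}: all predictors are epoch-indexed,
  so a continuous draw would be discretized anyway; the drawn times
  are used unsorted, which leaves the pair set unchanged.
* **CV caveat.** Seizure pairs sharing a seizure are not independent;
  the cross-validation treats pairs as exchangeable observations, as
  the analysis design prescribes. The permutation tests, which
  preserve the pair structure under the null, are the primary
  significance guard.

## What the synthetic generator emulates — and what it does not

`simulateRecording()` builds each channel as a sum over the five bands
of Butterworth-filtered white noise (4th order, zero-phase) whose
envelope is `exp(Σ_p loading_p(band, channel) · A_p · sin(2π t/P_p +
φ_p) + σ·η(t))`, tabulated at 30 s resolution and linearly
interpolated between epoch midpoints. This plants multiplicative
band-power rhythms exactly where the band-power stage measures them,
with channel/band loading patterns for the NMF stage, several
simultaneous periods for the MEMD stage, and an optional ±10% slow
period jitter to exercise nonstationarity tolerance.
`simulateSeizures()` draws onsets uniformly (distinct epochs), makes
each evolution a 40-step arc whose sweep and radius depend on the
weighted modulator state at onset, and exports the planted
dissimilarity `Σ_p w_p |state_p(t_a) − state_p(t_b)|` plus symmetric
noise.

The generator does **not** emulate: ictal waveforms or any
seizure-induced band-power transient; artefactual or dropped channels;
non-sinusoidal or asymmetric rhythms (e.g. sleep-stage square-wave
alternations); cross-channel phase coupling beyond shared modulators;
1/f background drift. Passing tests therefore demonstrate that the
pipeline recovers planted multiplicative rhythms and their association
with seizure-state distances under realistic noise — not that it is
robust to every artifact of clinical recordings.

Amplitude calibration is a free choice: the magnitude distribution of
real band-power fluctuations is not characterized in a way that could
be copied, so the default planted amplitude (1 on the log scale,
noise SD 0.2) was chosen once as a visible-but-noisy regime (log-power
fluctuation SD comparable to the rhythm amplitude).

## The desk-scale fixture

The canonical test subject is 4 channels at 192 Hz for 4 days
(T = 11,520 epochs), with a circadian (1 day) and an ultradian (6 h)
rhythm, each planted as two phase-shifted (π/2) copies on two channel
groups — mirroring the observation that different dimensions of a
circadian fluctuation need not share a phase, and giving the NMF
genuinely distinct spatial patterns. Eight seizures carry planted
dissimilarity weights 0.7 (circadian) / 0.3 (ultradian). These sizes
are the package's own desk-scale stand-in for clinical recordings
(24–128 channels, 512/1024 Hz, 2–12 days): 192 Hz is the smallest
rate that keeps the γ band below Nyquist, and 4 days is the shortest
span that resolves a circadian peak cleanly on a log-frequency axis.
Problem sizes used by the acceptance checks: MEMD completeness and
circadian detection at T = 11,520 (k selected from the data, 5 seeds);
dyadic filter-bank behaviour at T = 8,192, k = 3; regression recovery
at S = 8 seizures (28 pairs, 50 noise seeds; permutation tests at 200
iterations); null calibration over 100 replicates.

## Design choices where the design was genuinely open

* **NNSVD-LRC.** The initialization follows the cited construction:
  truncated SVD of rank ⌈k/2⌉+1, each subsequent rank-1 term split
  into its nonnegative sign parts ranked by energy, then a few cheap
  multiplicative-update passes against the clamped low-rank
  approximation. SVD signs are fixed deterministically
  (largest-magnitude entry positive) so the initialization — and
  everything downstream — is reproducible.
* **Refinement after initialization** always runs (Frobenius
  multiplicative updates): reproducible, monotone, standard.
* **Pearson** is used wherever "correlation" is unqualified.
* **Residue handling.** The residue is treated as one extra row in
  power, contribution and Gini summaries, and as one predictor in the
  regression; it is excluded from marginal spectra (it is a trend, not
  an oscillation).
* **p-values** use the plain strictly-greater percentage; the
  (b+1)/(n+1) correction is available behind a flag but is not the
  default, matching the analysis design as printed.
* **Identity permutations** are allowed in the shuffled-order null (a
  plain resampling reading).
* **Persistence** is delimited text + JSON sidecars throughout, so
  artifacts are diffable and a run directory can be resumed; each
  stage's manifest records its parameters and a resume aborts loudly
  on mismatch.

## Known limitations

* Mode mixing: EMD-family decompositions can split one rhythm across
  modes or merge nearby periods; slow-period ordering violations are
  logged, not fatal. Peak-frequency assignment of a planted rhythm to
  exactly one IMF index is therefore data-dependent.
* MU convergence: multiplicative updates plateau; exact-rank inputs
  reach ~1e-3 mean absolute error at the default budget, far from
  machine precision. Rank-1 inputs are recovered exactly by the
  initialization itself.
* The marginal spectrum is not smoothed before peak-picking; with few
  epochs the argmax bin can sit one bin away from the true frequency.
* Small-S regimes: with the minimum six seizures there are only 15
  pairs; CV folds are tiny and the LASSO path is noisy. The inclusion
  rule exists precisely because the design cannot support fewer.
* DTW dissimilarity operates on supplied evolution matrices; deriving
  functional-network evolutions from raw ictal EEG is outside this
  package's scope, and no additional normalization is applied to the
  evolution matrices before warping.
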