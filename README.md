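# seizmod

Subject-specific fluctuations in intracranial EEG band power — over
timescales from minutes to days — and their association with changes in
seizure evolutions.

## The scientific problem

Epilepsy is a dynamic disease: within one patient, the electrographic
evolution of seizures (how activity spreads and unfolds from onset to
termination) changes from one seizure to the next, and these changes
appear to follow circadian and slower modulatory processes. If such
modulators leave signatures in continuously recorded interictal EEG,
then cheap spectral features of the ongoing recording could serve as
markers of the processes that shape upcoming seizures.

`seizmod` implements a complete, testable pipeline for that question:

1. **Band power** — each channel's signal is cut into 30 s epochs and
   Welch band power is computed for δ (1–4), θ (4–8), α (8–13),
   β (13–30) and γ (30–80 Hz); per band, powers are log-transformed,
   standardised across all channels × epochs, and squashed with a
   sigmoid, giving the nonnegative data matrix
   `X ∈ [0,1]^(5·#channels × T)`.
2. **NMF** — `X ≈ W × H` with nonnegative factors, initialised by
   NNSVD-LRC (truncated-SVD sign-splitting with low-rank-correction
   refinement) and refined by Frobenius multiplicative updates. The
   rank k is selected over 3…15 as the smallest-redundancy solution
   `c = max{max|Corr[W]|, max|Corr[H]|}` among those with relative
   reconstruction error `Σ|X−X′|/(nT) < 0.05`.
3. **MEMD** — multivariate empirical mode decomposition of the k × T
   coefficient series H along quasi-uniform projection directions
   yields mode-aligned intrinsic mode functions (IMFs):
   `H_j(t) = Σ_i IMF_{i,j}(t) + r_j(t)`, from fast fluctuations
   (minutes) to slow trends (days).
4. **Hilbert–Huang spectra** — each IMF dimension's analytic signal
   gives instantaneous amplitude a(t) and frequency f(t); energies
   a²(t), averaged across dimensions, are accumulated over time into
   log-spaced frequency bins (cycles/day) to form marginal spectra,
   peak fluctuation frequencies, and the circadian IMF (peak period
   within 0.8–1.25 days; ties broken by total power).
5. **Contributions** — per-IMF relative dimension power
   `R_ij = E_ij/Σ_j E_ij` with `E_ij = Σ_t a²_ij(t)/T` weights the W
   basis columns into per-band percentage contributions and per-band
   channel-heterogeneity Gini indices
   `G(x) = 1 − 2 Σ_i (x_i/‖x‖₁)·(N−i+½)/N`.
6. **Seizure distances** — `X′_IMFi = W × IMF_i` reconstructs each
   timescale in channel/band space; for each seizure pair the Euclidean
   distance of `X′_IMFi` at the onset epochs gives one S × S distance
   matrix per IMF, plus residue and temporal distances.
7. **Association** — seizure dissimilarity (pairwise dynamic time
   warping of per-seizure evolution trajectories, mean cost along the
   optimal path) is regressed on the standardized distance predictors
   with a nonnegativity-constrained LASSO (10-fold CV over
   λ = 10⁻³…10², step 10^0.05), an OLS refit for coefficients, 95% CIs
   and adjusted R², and two permutation tests (random onset times;
   shuffled seizure order).

A synthetic-data module (`simulateRecording()`, `simulateSeizures()`,
`makeFixtures()`) plants multiplicative log-envelope modulators at
chosen periods, loadings and phases, plus seizures whose evolutions
depend on the modulator state at onset — so every stage above is
testable end-to-end with known ground truth and no data download.

## Worked example

```r
library(seizmod)

fx  <- makeFixtures(seed = 1)        # 4 ch, 192 Hz, 4 days, 8 seizures
bp  <- normalizeAndStack(fx$raw_power, epoch_s = fx$epoch_s)
run <- runPipeline(bp,
                   seizure_onsets = fx$seizures$onsets_s,
                   evolutions     = fx$seizures$evolutions,
                   config = pipelineConfig(n_perm = 200, seed = 1))

run$nmf
#> NMFFactorization: k = 4, n = 20, T = 11520
#>   rel. error = 0.03581, redundancy c = 0.5839

run$circadian_imf
#> [1] 10
round(run$peaks, 3)
#>  [1] 1024.275  549.014  323.904  191.095  102.428   60.430   32.390
#>  [8]   15.034    4.117    0.976    0.499    0.499    0.499

run$regression
#> RegressionResult: 28 obs, lambda = 0.1413, adj. R^2 = 0.6156
#>   selected: IMF2, IMF9, IMF10
#>   p (random onset times) = 0.045
#>   p (shuffled seizure order) = 0.025
```

Reading the output: rank selection keeps four spectral patterns; the
13 extracted IMFs peak from ~1000 cycles/day (minutes) down to ~0.5
cycles/day (2-day trends). IMF10 peaks at 0.976 cycles/day — the
planted circadian rhythm — and IMF9 at 4.1 cycles/day matches the
planted 6 h ultradian rhythm. The LASSO keeps the circadian (IMF10)
and ultradian (IMF9) seizure distances among its predictors, the OLS
refit explains ~62% of seizure-dissimilarity variance, and both
permutation tests call the association significant at the 5% level.

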