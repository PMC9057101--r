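# Session-level caches for expensive fixtures, computed once and shared
# across test files.

.fixture_cache <- new.env(parent = emptyenv())

# Full desk-scale fixture pipeline, cached per seed: synthetic band
# power (streamed), then the orchestrated pipeline on the stacked
# matrix (NMF -> MEMD -> HHT -> contributions -> distances ->
# regression without permutations).
fixtureRun <- function(seed = 1) {
  key <- paste0("run", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fx <- makeFixtures(seed)
  bp <- normalizeAndStack(fx$raw_power, epoch_s = fx$epoch_s)
  pr <- suppressWarnings(suppressMessages(runPipeline(
    bp, seizure_onsets = fx$seizures$onsets_s,
    evolutions = fx$seizures$evolutions,
    config = pipelineConfig(n_perm = 0, seed = seed))))
  run <- list(fx = fx, bp = bp, fact = pr$nmf, imfset = pr$imfset,
              spectrum = pr$spectrum, pipeline = pr, seed = seed)
  .fixture_cache[[key]] <- run
  gc(FALSE)
  run
}

# Miniature half-day subject for the orchestration tests, cached.
miniSubjectCached <- function(seed = 31) {
  key <- paste0("mini", seed)
  if (is.null(.fixture_cache[[key]])) {
    mods <- list(
      modulatorSpec(0.05, amplitude = 1, phase = 0.4,
                    loading = bandLoading(c("delta", "theta"), 1:2, 2, 0.9)),
      modulatorSpec(0.2, amplitude = 1, phase = 2,
                    loading = bandLoading(c("beta", "gamma"), 1:2, 2, 0.9)))
    rec <- simulateRecording(2, 192, 0.5, mods, noise_sd = 0.1, seed = seed)
    sz <- simulateSeizures(mods, 0.5, 8, weights = c(0.7, 0.3),
                           noise_sd = 0.05, seed = seed + 1)
    .fixture_cache[[key]] <- attachSeizures(rec, sz)
  }
  .fixture_cache[[key]]
}

# Small recording with one fast modulator (loading 1 on delta), used by
# the generator-oracle tests; 2 channels, half a day.
smallRecording <- function(seed = 7, period = 0.1, amplitude = 1,
                           noise_sd = 0.05, duration_days = 0.5,
                           loading = NULL, jitter = FALSE) {
  if (is.null(loading)) loading <- bandLoading("delta", 1:2, 2, 1)
  m <- modulatorSpec(period = period, amplitude = amplitude, phase = 1,
                     loading = loading, jitter = jitter)
  simulateRecording(n_channels = 2, fs = 192,
                    duration_days = duration_days,
                    modulators = list(m), noise_sd = noise_sd,
                    seed = seed)
}

# Independent band-pass + magnitude oracle for log-envelopes at epoch
# resolution: filters with signal::filtfilt (not the package's compiled
# path) and takes 30 s RMS of the band-passed signal.
oracleLogEnvelope <- function(x, fs, lo, hi, epoch_s = 30) {
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  len <- fs * epoch_s
  nT <- length(y) %/% len
  v <- vapply(seq_len(nT) - 1, function(t)
    sqrt(mean(y[(t * len + 1):((t + 1) * len)]^2)), numeric(1))
  log(v)
}

# Standardize a vector (helper mirroring the package's rule).
zstd <- function(v) (v - mean(v)) / sd(v)

# Build a RegressionDataset directly from a response and predictor
# matrix (already vectorized seizure pairs).
datasetFromMatrix <- function(y, Z, labels = colnames(Z)) {
  if (is.null(labels)) labels <- sprintf("P%d", seq_len(ncol(Z)))
  Zs <- apply(Z, 2, zstd)
  colnames(Zs) <- labels
  new("RegressionDataset", y = zstd(y), Z = Zs, labels = labels,
      dropped = character(0), pairs = cbind(1L, 1L),
      degenerate = FALSE)
}
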