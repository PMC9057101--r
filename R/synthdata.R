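#' @include AllClasses.R
NULL

#' Construct a modulator specification
#'
#' A planted latent rhythm for the synthetic generator: log band power is
#' modulated by `amplitude * sin(2*pi*t/period + phase)`, weighted per
#' band and channel by the `loading` matrix.
#'
#' @param period period in days.
#' @param amplitude dimensionless amplitude (default 1).
#' @param phase radians in [0, 2*pi) (default 0).
#' @param loading 5 x #channels matrix with entries in [0, 1], or NULL
#'   for uniform loading 1 (requires `n_channels`).
#' @param n_channels used when `loading` is NULL.
#' @param jitter add a +/-10% slow random-walk period jitter
#'   (default FALSE).
#' @return A \linkS4class{ModulatorSpec}.
#' @export
modulatorSpec <- function(period, amplitude = 1, phase = 0, loading = NULL,
                          n_channels = NULL, jitter = FALSE) {
  if (is.null(loading)) {
    if (is.null(n_channels)) stop("supply loading or n_channels")
    loading <- matrix(1, 5, n_channels)
  }
  new("ModulatorSpec", period = period, amplitude = amplitude,
      phase = phase, loading = loading, jitter = jitter)
}

#' Loading matrix helper
#'
#' Builds a 5 x #channels loading matrix with `value` on the given bands
#' and channels and 0 elsewhere.
#'
#' @param bands band names or indices (1 = delta ... 5 = gamma).
#' @param channels channel indices.
#' @param n_channels total channels.
#' @param value loading weight (default 1).
#' @return 5 x n_channels matrix.
#' @export
bandLoading <- function(bands, channels, n_channels, value = 1) {
  L <- matrix(0, 5, n_channels)
  if (is.character(bands)) bands <- match(bands, defaultBands()$name)
  L[bands, channels] <- value
  L
}

# Latent modulator state time series at given times (days).
# state_p(t) = amplitude * sin(2*pi*t/period + phase); with jitter the
# instantaneous frequency wanders +/-10% as a smoothed random walk
# (seeded), integrated into the phase.
modulatorStates <- function(modulators, t_days, seed = 0) {
  P <- length(modulators)
  states <- matrix(0, P, length(t_days))
  for (p in seq_len(P)) {
    m <- modulators[[p]]
    if (isTRUE(m@jitter)) {
      z <- withSeed(deriveSeed(seed, 900 + p), {
        w <- cumsum(rnorm(length(t_days)))
        w <- w / max(abs(w), 1e-12)
        stats::filter(w, rep(1 / 25, 25), circular = TRUE)
      })
      f_inst <- (1 / m@period) * (1 + 0.1 * as.numeric(z))
      dt <- c(0, diff(t_days))
      phase <- 2 * pi * cumsum(f_inst * dt) + m@phase
      states[p, ] <- m@amplitude * sin(phase)
    } else {
      states[p, ] <- m@amplitude * sin(2 * pi * t_days / m@period + m@phase)
    }
  }
  states
}

#' Generate a synthetic multichannel recording with planted modulators
#'
#' Each channel is a sum over the five EEG bands of band-limited noise
#' (white noise through a 4th-order zero-phase Butterworth band-pass)
#' whose amplitude envelope is
#' `exp(sum_p loading_p(b, c) * state_p(t) + noise)`, with the latent
#' states `state_p(t) = amplitude_p * sin(2*pi*t/period_p + phase_p)`.
#' The envelope is tabulated at 30 s (epoch) resolution and linearly
#' interpolated to sample resolution between epoch midpoints. Deterministic given the seed; the ground truth (specs,
#' latent state series, seed) is stored in `truth`.
#'
#' @param n_channels number of channels (>= 2).
#' @param fs sampling rate, Hz (> 160 so the gamma band exists).
#' @param duration_days recording length in days (>= 0.5).
#' @param modulators list of \linkS4class{ModulatorSpec} (>= 1).
#' @param noise_sd SD of the per-epoch log-envelope noise (default 0.1).
#' @param seed integer seed.
#' @param epoch_s envelope resolution, seconds (default 30).
#' @param bands band definitions.
#' @return A \linkS4class{SyntheticRecording} (no seizures attached).
#' @export
simulateRecording <- function(n_channels = 4, fs = 192, duration_days = 4,
                              modulators = list(), noise_sd = 0.1, seed = 1,
                              epoch_s = 30, bands = defaultBands()) {
  stopifnot(n_channels >= 2, duration_days >= 0.5)
  if (!length(modulators)) stop("at least one modulator required")
  checkBands(bands, fs)
  for (m in modulators) {
    validObject(m)
    if (ncol(m@loading) != n_channels)
      stop("modulator loading does not match n_channels")
  }
  n <- round(duration_days * 86400 * fs)
  nT <- n %/% round(fs * epoch_s)
  t_mid <- ((seq_len(nT) - 0.5) * epoch_s) / 86400
  states <- modulatorStates(modulators, t_mid, seed)
  signals <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels))
    signals[ch, ] <- channelSignal(ch, n, nT, fs, bands, modulators,
                                   states, noise_sd, seed, epoch_s)
  new("SyntheticRecording",
      signals = signals, fs = fs,
      channelNames = sprintf("ch%02d", seq_len(n_channels)),
      epoch_s = epoch_s,
      seizureOnsets = numeric(0), seizureEvolutions = list(),
      truth = list(modulators = modulators, states = states,
                   state_times_days = t_mid, noise_sd = noise_sd,
                   seed = seed))
}

# One channel's signal: the sum over bands of Butterworth band-limited
# noise times the exponentiated log-envelope (epoch grid, linearly
# interpolated to samples). Per-channel RNG substream so that batch and
# streaming generation agree sample for sample.
channelSignal <- function(ch, n, nT, fs, bands, modulators, states,
                          noise_sd, seed, epoch_s) {
  nb <- nrow(bands)
  filts <- lapply(seq_len(nb), function(b)
    signal::butter(4, c(bands$lo[b], bands$hi[b]) / (fs / 2), type = "pass"))
  withSeed(deriveSeed(seed, 100 + ch), {
    white <- rnorm(n)
    logenv <- matrix(0, nb, nT)
    for (b in seq_len(nb)) {
      for (p in seq_along(modulators))
        logenv[b, ] <- logenv[b, ] + modulators[[p]]@loading[b, ch] * states[p, ]
      if (noise_sd > 0) logenv[b, ] <- logenv[b, ] + noise_sd * rnorm(nT)
    }
    sig <- .cpp_channel_signal(white, lapply(filts, `[[`, "b"),
                               lapply(filts, `[[`, "a"),
                               logenv, epoch_s * fs)
    dim(sig) <- NULL  # column-matrix wrapper off, no copy
    sig
  })
}

#' Memory-lean synthetic band power
#'
#' Generates the same per-channel signals as [simulateRecording()] (one
#' channel at a time, identical given the seed) but immediately reduces
#' each channel to its Welch band-power series and discards the raw
#' samples, so multi-day recordings never hold the full signal matrix in
#' memory.
#'
#' @inheritParams simulateRecording
#' @param seg_s Welch segment length, seconds.
#' @return List: `raw_power` (#bands x #channels x #epochs), `states`
#'   (modulator states at epoch midpoints), `t_mid_days`, `nT`.
#' @export
simulateBandPower <- function(n_channels = 4, fs = 192, duration_days = 4,
                              modulators = list(), noise_sd = 0.1, seed = 1,
                              epoch_s = 30, bands = defaultBands(),
                              seg_s = 3) {
  stopifnot(n_channels >= 2, duration_days >= 0.5)
  if (!length(modulators)) stop("at least one modulator required")
  checkBands(bands, fs)
  n <- round(duration_days * 86400 * fs)
  nT <- n %/% round(fs * epoch_s)
  t_mid <- ((seq_len(nT) - 0.5) * epoch_s) / 86400
  states <- modulatorStates(modulators, t_mid, seed)
  raw <- array(NA_real_, dim = c(nrow(bands), n_channels, nT),
               dimnames = list(bands$name,
                               sprintf("ch%02d", seq_len(n_channels)), NULL))
  for (ch in seq_len(n_channels)) {
    sig <- channelSignal(ch, n, nT, fs, bands, modulators, states,
                         noise_sd, seed, epoch_s)
    raw[, ch, ] <- welchPowerSeries(sig, fs, bands, epoch_s, seg_s)[, 1, ]
    rm(sig)
    gc(FALSE)  # release the channel's large buffers promptly
  }
  list(raw_power = raw, states = states, t_mid_days = t_mid, nT = nT)
}

# Evolution trajectory for a scalar shape parameter g: an arc whose
# sweep angle and radius depend on g; minimal structure sufficient for
# dynamic time warping. 40 steps, feature dimension >= 2.
seizureArc <- function(g, evolution_dim = 2, n_steps = 40) {
  u <- seq(0, 1, length.out = n_steps)
  theta <- (pi / 2 + 0.8 * tanh(g)) * u
  r <- 1 + 0.5 * tanh(g)
  out <- cbind(r * cos(theta), r * sin(theta))
  d <- 2
  while (d < evolution_dim) {
    d <- d + 1
    out <- cbind(out, 0.5 * r * sin(d * theta / 2))
  }
  out
}

#' Generate seizure onsets, evolutions and the planted dissimilarity
#'
#' Seizure onsets are drawn uniformly over the recording span (distinct
#' epochs, strictly increasing). Each seizure's evolution is a smooth
#' 2-D (or higher) arc whose shape parameter is the weighted sum of the
#' modulator states at its onset plus Gaussian noise; the planted
#' dissimilarity is `sum_p w_p |state_p(t_a) - state_p(t_b)|` plus
#' symmetric noise (clamped nonnegative, zero diagonal).
#'
#' @param modulators list of \linkS4class{ModulatorSpec}.
#' @param span_days recording span the onsets must fall into.
#' @param n_seizures number of seizures (>= 2).
#' @param evolution_dim feature dimension of evolutions (default 2).
#' @param weights per-modulator weights (default equal).
#' @param noise_sd SD of shape and dissimilarity noise (default 0.1).
#' @param seed integer seed.
#' @param epoch_s epoch duration, seconds.
#' @param n_steps evolution length in time steps (default 40).
#' @return List: `onsets_s`, `evolutions`, `planted` (S x S), `states`
#'   (modulator states at onsets), `g` (shape parameters), `weights`.
#' @export
simulateSeizures <- function(modulators, span_days, n_seizures = 8,
                             evolution_dim = 2, weights = NULL,
                             noise_sd = 0.1, seed = 1, epoch_s = 30,
                             n_steps = 40) {
  if (n_seizures < 2) stop("need at least two seizures")
  P <- length(modulators)
  if (is.null(weights)) weights <- rep(1, P)
  stopifnot(length(weights) == P, all(weights >= 0))
  nT <- floor(span_days * 86400 / epoch_s)
  out <- withSeed(seed, {
    ep <- sort(sample.int(nT - 1L, n_seizures))  # distinct, ascending, >0
    onsets_s <- ep * epoch_s + epoch_s / 2
    t_days <- onsets_s / 86400
    states <- modulatorStates(modulators, t_days, seed)
    g <- drop(weights %*% states) +
      if (noise_sd > 0) noise_sd * rnorm(n_seizures) else 0
    evolutions <- lapply(g, seizureArc, evolution_dim = evolution_dim,
                         n_steps = n_steps)
    planted <- matrix(0, n_seizures, n_seizures)
    for (p in seq_len(P))
      planted <- planted + weights[p] * abs(outer(states[p, ], states[p, ], "-"))
    if (noise_sd > 0) {
      eps <- matrix(rnorm(n_seizures^2, sd = noise_sd), n_seizures)
      eps <- (eps + t(eps)) / 2
      diag(eps) <- 0
      planted <- pmax(planted + eps, 0)
      diag(planted) <- 0
    }
    list(onsets_s = onsets_s, evolutions = evolutions, planted = planted,
         states = states, g = g, weights = weights)
  })
  out
}

#' Attach seizures to a synthetic recording
#'
#' @param recording a \linkS4class{SyntheticRecording}.
#' @param seizures output of [simulateSeizures()].
#' @return The recording with seizure fields and truth updated.
#' @export
attachSeizures <- function(recording, seizures) {
  recording@seizureOnsets <- seizures$onsets_s
  recording@seizureEvolutions <- seizures$evolutions
  recording@truth$seizures <- seizures[c("planted", "states", "g", "weights")]
  validObject(recording)
  recording
}

#' The package's desk-scale synthetic fixture subject
#'
#' A deterministic synthetic subject used throughout the test suite:
#' 4 channels at 192 Hz for 4 days (T = 11,520 epochs of 30 s), with a
#' circadian modulator (period 1 day, loaded on delta/theta/alpha
#' across all channels) and an ultradian modulator (period 6 h, loaded
#' on beta/gamma), and 8 seizures whose planted dissimilarity weights
#' the circadian and ultradian states 0.7/0.3.
#'
#' The default fixture streams channels through the band-power stage
#' ([simulateBandPower()]) so the multi-day signal matrix never needs to
#' be held in memory; `keep_signals = TRUE` additionally returns the
#' full \linkS4class{SyntheticRecording} (identical samples, same seed).
#'
#' @param seed integer seed.
#' @param n_channels,fs,duration_days,n_seizures scale overrides.
#' @param noise_sd log-envelope noise SD (default 0.2).
#' @param keep_signals also build the raw-signal recording object.
#' @return List: `raw_power` (5 x C x T array), `states`, `seizures`,
#'   `modulators`, `fs`, `epoch_s`, `duration_days`, `seed`, and
#'   `recording` (NULL unless `keep_signals`).
#' @export
makeFixtures <- function(seed = 1, n_channels = 4, fs = 192,
                         duration_days = 4, n_seizures = 8,
                         noise_sd = 0.2, keep_signals = FALSE) {
  # channel groups with phase-shifted copies of each rhythm: gives NMF
  # spatially distinct patterns (as phase differences between dimensions
  # do in real recordings) while MEMD still sees one fluctuation per
  # timescale across dimensions
  grpA <- seq_len(ceiling(n_channels / 2))
  grpB <- setdiff(seq_len(n_channels), grpA)
  circ <- modulatorSpec(
    period = 1, amplitude = 1, phase = 0.7,
    loading = bandLoading(c("delta", "theta", "alpha"), grpA,
                          n_channels, 0.9) +
      bandLoading("beta", grpA, n_channels, 0.3))
  circB <- modulatorSpec(
    period = 1, amplitude = 1, phase = 0.7 + pi / 2,
    loading = bandLoading(c("delta", "theta", "alpha"), grpB,
                          n_channels, 0.9))
  ultr <- modulatorSpec(
    period = 0.25, amplitude = 1, phase = 2.1,
    loading = bandLoading(c("beta", "gamma"), grpA, n_channels, 0.9) +
      bandLoading("delta", grpA, n_channels, 0.2))
  ultrB <- modulatorSpec(
    period = 0.25, amplitude = 1, phase = 2.1 + pi / 2,
    loading = bandLoading(c("beta", "gamma"), grpB, n_channels, 0.9))
  mods <- list(circ, circB, ultr, ultrB)
  sim <- simulateBandPower(n_channels, fs, duration_days, mods,
                           noise_sd = noise_sd, seed = seed)
  sz <- simulateSeizures(mods, duration_days, n_seizures,
                         weights = c(0.7, 0, 0.3, 0), noise_sd = 0.05,
                         seed = deriveSeed(seed, 17))
  rec <- NULL
  if (keep_signals) {
    rec <- simulateRecording(n_channels, fs, duration_days, mods,
                             noise_sd = noise_sd, seed = seed)
    rec <- attachSeizures(rec, sz)
  }
  list(raw_power = sim$raw_power, states = sim$states,
       t_mid_days = sim$t_mid_days, seizures = sz,
       modulators = list(circadian = circ, ultradian = ultr),
       fs = fs, epoch_s = 30, duration_days = duration_days,
       seed = seed, recording = rec)
}
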