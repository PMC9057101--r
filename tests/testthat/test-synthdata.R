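test_that("modulator and recording constructors validate their invariants", {
  expect_error(modulatorSpec(period = -1, n_channels = 2), "period")
  expect_error(modulatorSpec(1, amplitude = -2, n_channels = 2), "amplitude")
  expect_error(modulatorSpec(1, phase = 7, n_channels = 2), "phase")
  L <- bandLoading("delta", 1:2, 2, 2)   # loading > 1
  expect_error(modulatorSpec(1, loading = L), "loading")
  m <- modulatorSpec(1, n_channels = 2)
  expect_error(simulateRecording(1, 192, 1, list(m)), "n_channels")
  expect_error(simulateRecording(2, 192, 0.1, list(m)), "duration")
  expect_error(simulateRecording(2, 192, 1, list()), "modulator")
  # gamma band must fit below Nyquist, refused by band name
  expect_error(simulateRecording(2, 120, 1, list(m)), "gamma")
})

test_that("generation is deterministic and batch equals streaming", {
  m <- modulatorSpec(0.05, amplitude = 1, phase = 1,
                     loading = bandLoading(1:5, 1:2, 2, 0.5))
  r1 <- simulateRecording(2, 192, 0.5, list(m), noise_sd = 0.1, seed = 9)
  r2 <- simulateRecording(2, 192, 0.5, list(m), noise_sd = 0.1, seed = 9)
  expect_identical(r1@signals, r2@signals)
  # streaming band-power route sees exactly the same channels
  sim <- simulateBandPower(2, 192, 0.5, list(m), noise_sd = 0.1, seed = 9)
  raw <- welchPowerSeries(r1@signals, 192)
  expect_equal(as.vector(sim$raw_power), as.vector(raw), tolerance = 1e-12)
})

test_that("a planted daily rhythm appears in the realized delta log-envelope", {
  rec <- smallRecording(seed = 7, period = 1, amplitude = 1,
                        noise_sd = 0.1, duration_days = 1)
  env <- oracleLogEnvelope(rec@signals[1, ], 192, 1, 4)
  planted <- rec@truth$states[1, ]
  expect_gte(cor(env, planted), 0.9)
  # unloaded band (gamma) carries no rhythm: its realized band power
  # (package route) is uncorrelated with the planted state
  envg <- log(welchPowerSeries(rec@signals[1, ], 192)[5, 1, ])
  expect_lt(abs(cor(envg, planted)), 0.35)
})

test_that("zero-amplitude modulators leave no rhythm to fit", {
  rec <- smallRecording(seed = 8, period = 0.1, amplitude = 0,
                        noise_sd = 0.05)
  env <- oracleLogEnvelope(rec@signals[1, ], 192, 1, 4)
  t_days <- (seq_along(env) - 0.5) * 30 / 86400
  # sinusoidal fit at the (would-be) planted frequency explains nothing
  fit <- lm(env ~ sin(2 * pi * t_days / 0.1) + cos(2 * pi * t_days / 0.1))
  expect_lt(summary(fit)$r.squared, 0.05)
})

test_that("periodogram of a loaded band power series peaks at the planted period", {
  # period 0.1 day over half a day: 5 cycles planted
  rec <- smallRecording(seed = 10, period = 0.1, amplitude = 1,
                        noise_sd = 0.05)
  raw <- welchPowerSeries(rec@signals, 192)
  v <- log(raw[1, 1, ])   # delta, loaded channel
  sp <- stats::spec.pgram(stats::ts(v, frequency = 2880), plot = FALSE,
                          taper = 0, detrend = TRUE)
  pk <- sp$freq[which.max(sp$spec)]
  df <- diff(sp$freq[1:2])
  expect_lte(abs(pk - 10), df + 1e-9)   # within one frequency bin
})

test_that("period jitter perturbs but does not destroy the planted rhythm", {
  rec <- smallRecording(seed = 11, period = 0.1, amplitude = 1,
                        noise_sd = 0.05, jitter = TRUE)
  env <- oracleLogEnvelope(rec@signals[1, ], 192, 1, 4)
  expect_gte(cor(env, rec@truth$states[1, ]), 0.8)
})

test_that("seizure schedules, evolutions and planted dissimilarity obey their contracts", {
  m1 <- modulatorSpec(1, phase = 0.3, n_channels = 2)
  m2 <- modulatorSpec(0.25, phase = 2, n_channels = 2)
  sz <- simulateSeizures(list(m1, m2), span_days = 4, n_seizures = 8,
                         weights = c(0.7, 0.3), noise_sd = 0.1, seed = 3)
  expect_length(sz$onsets_s, 8)
  expect_length(sz$evolutions, 8)
  expect_true(all(diff(sz$onsets_s) > 0))
  expect_true(all(sz$onsets_s >= 0 & sz$onsets_s < 4 * 86400))
  expect_equal(sz$planted, t(sz$planted))
  expect_equal(diag(sz$planted), rep(0, 8))
  expect_error(simulateSeizures(list(m1), 4, n_seizures = 1), "two")
  # determinism
  sz2 <- simulateSeizures(list(m1, m2), 4, 8, weights = c(0.7, 0.3),
                          noise_sd = 0.1, seed = 3)
  expect_identical(sz, sz2)
  # planted dissimilarity tracks the true modulator-state distance
  truth <- 0.7 * abs(outer(sz$states[1, ], sz$states[1, ], "-")) +
    0.3 * abs(outer(sz$states[2, ], sz$states[2, ], "-"))
  ut <- upper.tri(truth)
  expect_gte(cor(sz$planted[ut], truth[ut], method = "spearman"), 0.9)
})

test_that("noise-free seizures at identical modulator phase coincide", {
  m <- modulatorSpec(0.25, phase = 1, n_channels = 2)
  # craft a span where two drawn onsets land one period apart: use
  # noise_sd = 0 and check pairs with equal states directly
  sz <- simulateSeizures(list(m), 2, n_seizures = 6, noise_sd = 0, seed = 5)
  s <- sz$states[1, ]
  for (a in 1:5) for (b in (a + 1):6) {
    if (abs(s[a] - s[b]) < 1e-12) {
      expect_equal(sz$planted[a, b], 0)
      expect_equal(sz$evolutions[[a]], sz$evolutions[[b]])
    }
  }
  # same phase forced: duplicate modulator states via equal onsets is
  # impossible (strictly increasing), so verify directly that the arc
  # generator is a deterministic function of its shape parameter
  expect_identical(seizmod:::seizureArc(0.4), seizmod:::seizureArc(0.4))
  expect_false(identical(seizmod:::seizureArc(0.4), seizmod:::seizureArc(-0.2)))
})

test_that("recordings round-trip through the binary + sidecar writer", {
  rec <- smallRecording(seed = 12)
  m1 <- modulatorSpec(0.1, phase = 1, loading = bandLoading("delta", 1:2, 2))
  sz <- simulateSeizures(list(m1), 0.5, n_seizures = 6, seed = 4)
  rec <- attachSeizures(rec, sz)
  dir <- file.path(tempdir(), "recdir")
  writeRecording(rec, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "signals.bin", "recording.json", "seizures.csv", "truth.json")))))
  back <- readRecording(dir)
  expect_equal(dim(back@signals), dim(rec@signals))
  # float32 round trip: relative error at single precision
  expect_lt(max(abs(back@signals - rec@signals)) / sd(rec@signals), 1e-6)
  expect_equal(back@seizureOnsets, rec@seizureOnsets)
  expect_length(back@seizureEvolutions, 6)
  expect_equal(back@seizureEvolutions[[2]], unname(rec@seizureEvolutions[[2]]),
               tolerance = 1e-12)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$modulators[[1]]$period, 0.1)
  unlink(dir, recursive = TRUE)
})
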