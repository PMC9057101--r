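test_that("epoching is sample-exact, contiguous, and truncates trailing data", {
  fs <- 50
  x <- matrix(seq_len(2 * 300 * fs), nrow = 2, byrow = TRUE)
  e <- epochSignal(x, fs, 30)
  expect_length(e, 10)                       # 300 s -> 10 epochs
  # 305 s -> still 10 epochs, 5 s discarded
  x2 <- matrix(rnorm(2 * 305 * fs), nrow = 2)
  expect_length(epochSignal(x2, fs, 30), 10)
  # epoch t covers samples [t*fs*epoch_s, (t+1)*fs*epoch_s), 0-based
  expect_equal(e[[1]][1, ], seq_len(30 * fs))
  expect_equal(e[[3]][1, ], 2 * 30 * fs + seq_len(30 * fs))
  expect_error(epochSignal(rnorm(10), fs, 30), "shorter")
})

test_that("Welch band power matches sinusoid and flat-spectrum oracles", {
  fs <- 256
  t <- (0:(30 * fs - 1)) / fs
  # all-zero epoch -> all zero powers
  expect_equal(unname(welchBandPower(numeric(30 * fs), fs)), rep(0, 5))
  # unit 10 Hz sinusoid: alpha power ~ variance 0.5, others < 1% of it
  p <- welchBandPower(sin(2 * pi * 10 * t), fs)
  expect_equal(unname(p["alpha"]), 0.5, tolerance = 0.01)
  expect_true(all(p[c("delta", "theta", "beta", "gamma")] < 0.01 * p["alpha"]))
  # white noise: total band power ~ sigma^2 * (79/128) for fs 256
  set.seed(8)
  x <- rnorm(30 * fs, sd = 1.3)
  expect_equal(sum(welchBandPower(x, fs)) / var(x), 79 / 128,
               tolerance = 0.05)
  # a band reaching past Nyquist is refused by name
  bad <- defaultBands(); bad$hi[5] <- 200
  expect_error(welchBandPower(x, fs, bad), "gamma")
})

test_that("the compiled power series equals per-epoch Welch computation", {
  fs <- 192
  set.seed(3)
  sig <- matrix(rnorm(2 * 90 * fs), nrow = 2)
  raw <- welchPowerSeries(sig, fs)
  for (t in 1:3) {
    ep <- sig[, ((t - 1) * 30 * fs + 1):(t * 30 * fs)]
    for (ch in 1:2)
      expect_equal(raw[, ch, t], welchBandPower(ep[ch, ], fs),
                   tolerance = 1e-12)
  }
})

test_that("normalization produces pooled z-scores, sigmoid range, and monotonicity", {
  set.seed(4)
  raw <- array(rexp(5 * 3 * 40), dim = c(5, 3, 40))
  bp <- normalizeAndStack(raw)
  X <- SummarizedExperiment::assay(bp)
  expect_equal(dim(X), c(15, 40))
  expect_true(all(X > 0 & X < 1))
  # undo the sigmoid: each band's pooled z-scores have mean 0, SD 1
  z <- log(X / (1 - X))
  for (b in 1:5) {
    rows <- (b - 1) * 3 + 1:3
    expect_equal(mean(z[rows, ]), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(z[rows, ])), 1, tolerance = 1e-10)
  }
  # z = 0 maps to 0.5
  expect_equal(1 / (1 + exp(0)), 0.5)
  # monotone: larger raw power within a band -> larger stacked value
  o_raw <- order(raw[2, , ])
  o_stacked <- order(as.vector(X[4:6, ]))
  expect_equal(o_raw, o_stacked)
  # degenerate input refused
  raw0 <- raw; raw0[1, , ] <- 1
  expect_error(normalizeAndStack(raw0), "degenerate")
})

test_that("row order is band-major and permutation-equivariant", {
  set.seed(5)
  raw <- array(rexp(5 * 4 * 30), dim = c(5, 4, 30),
               dimnames = list(defaultBands()$name,
                               paste0("c", 1:4), NULL))
  bp <- normalizeAndStack(raw)
  rd <- SummarizedExperiment::rowData(bp)
  expect_equal(rd$band, rep(defaultBands()$name, each = 4))
  expect_equal(nrow(bp), 5 * 4)
  # permuting channels permutes rows within each band block
  perm <- c(3, 1, 4, 2)
  bp2 <- normalizeAndStack(raw[, perm, ], channels = paste0("c", perm))
  X <- SummarizedExperiment::assay(bp)
  X2 <- SummarizedExperiment::assay(bp2)
  for (b in 1:5)
    expect_equal(unname(X2[(b - 1) * 4 + 1:4, ]),
                 unname(X[(b - 1) * 4 + perm, ]))
})

test_that("band-power rows carry a planted circadian rhythm to the periodogram", {
  run <- fixtureRun(1)
  X <- SummarizedExperiment::assay(run$bp)
  # delta row of a group-A channel; 1 cycle/day planted
  v <- X[1, ]
  sp <- stats::spec.pgram(stats::ts(v, frequency = 2880), plot = FALSE,
                          taper = 0, detrend = TRUE)
  pk <- sp$freq[which.max(sp$spec)]   # cycles/day
  expect_lt(abs(pk - 1), 0.3)
})
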