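cosineImfSet <- function(Tn = 2880 * 4, k = 2, period_epochs = 2880,
                         amp = 1) {
  x <- amp * cos(2 * pi * seq_len(Tn) / period_epochs)
  arr <- array(0, dim = c(1, k, Tn))
  for (j in seq_len(k)) arr[1, j, ] <- x
  new("IMFSet", imfs = arr, residue = matrix(0, k, Tn),
      epochDuration = 30, params = list())
}

test_that("analytic signal matches the closed form of a cosine", {
  Tn <- 2880 * 4   # 4 days at 30 s epochs
  x <- cos(2 * pi * seq_len(Tn) / 2880)   # 1 cycle/day
  tr <- analyticSignal(x, 30)
  expect_lt(max(abs(tr@amplitude[tr@validMask] - 1)), 0.01)
  expect_lt(max(abs(tr@instFreq[tr@validMask] - 1)), 0.01)
  # zero input: zero amplitude, nothing valid
  tr0 <- analyticSignal(numeric(64), 30)
  expect_equal(max(tr0@amplitude), 0)
  expect_false(any(tr0@validMask))
  expect_error(analyticSignal(c(1, NA, 3, rep(0, 20))), "finite")
  expect_error(analyticSignal(rnorm(8)), "short")
})

test_that("instantaneous frequency tracks a linear chirp within 5%", {
  Tn <- 2880 * 4
  t_days <- seq_len(Tn) * 30 / 86400
  # 2 -> 4 cycles/day over 4 days: phase = 2*pi*(2 t + t^2/4)
  phase <- 2 * pi * (2 * t_days + t_days^2 / 4)
  tr <- analyticSignal(cos(phase), 30)
  f_true <- 2 + t_days / 2
  rel <- abs(tr@instFreq - f_true) / f_true
  expect_lt(max(rel[tr@validMask]), 0.05)
})

test_that("marginal spectrum concentrates sinusoid energy and conserves it", {
  im <- cosineImfSet()
  ms <- marginalSpectrum(im)
  d <- ms@density[1, ]
  ctr <- sqrt(ms@binEdges[-length(ms@binEdges)] * ms@binEdges[-1])
  peak_bin <- which.max(d)
  expect_lt(abs(log10(ctr[peak_bin])), log10(10^(1 / 48)) + 1e-9)
  # >= 100x any bin more than a factor 2 away in frequency
  far <- which(ctr < ctr[peak_bin] / 2 | ctr > ctr[peak_bin] * 2)
  expect_true(all(d[far] <= d[peak_bin] / 100))
  # energy conservation against the valid-mask amplitude sum
  tr <- analyticSignal(im@imfs[1, 1, ], 30)
  ok <- tr@validMask
  expect_equal(sum(d), sum(tr@amplitude[ok]^2), tolerance = 1e-9)
  # doubling amplitude quadruples every bin
  ms2 <- marginalSpectrum(cosineImfSet(amp = 2))
  nz <- ms@density[1, ] > 0
  expect_equal(ms2@density[1, nz], 4 * ms@density[1, nz],
               tolerance = 1e-9)
})

test_that("peak frequency picks the argmax bin centre with the documented tie-break", {
  im <- cosineImfSet()
  ms <- marginalSpectrum(im)
  pk <- peakFrequency(ms, 1)
  expect_equal(pk, 1, tolerance = 10^(1 / 48) - 1)
  # scale invariance of the peak location
  expect_equal(peakFrequency(marginalSpectrum(cosineImfSet(amp = 3)), 1), pk)
  # tie -> lower frequency with a warning
  ms2 <- ms
  dens <- ms2@density
  b <- which.max(dens[1, ])
  dens[1, b + 10] <- dens[1, b]
  ms2@density <- dens
  expect_warning(pk2 <- peakFrequency(ms2, 1), "tie")
  expect_equal(pk2, pk)
  ms3 <- ms; ms3@density[1, ] <- 0
  expect_error(peakFrequency(ms3, 1), "all-zero")
})

test_that("circadian IMF detection follows the band and higher-power rules", {
  Tn <- 2880 * 4
  mk <- function(period_epochs, amp) amp * cos(2 * pi * seq_len(Tn) / period_epochs)
  arr <- array(0, dim = c(3, 1, Tn))
  arr[1, 1, ] <- mk(240, 1)      # 12 cycles/day
  arr[2, 1, ] <- mk(2880, 1)     # circadian
  arr[3, 1, ] <- mk(8640, 1)     # 3-day cycle
  im <- new("IMFSet", imfs = arr, residue = matrix(0, 1, Tn),
            epochDuration = 30, params = list())
  ms <- marginalSpectrum(im)
  expect_equal(findCircadianImf(ms), 2L)
  # two in-band peaks: the higher-power one wins
  arr2 <- arr
  arr2[1, 1, ] <- mk(2880 * 1.05, sqrt(3))   # in-band, 3x power
  im2 <- new("IMFSet", imfs = arr2, residue = matrix(0, 1, Tn),
             epochDuration = 30, params = list())
  expect_equal(findCircadianImf(marginalSpectrum(im2)), 1L)
  # all peaks outside the band -> absent with a diagnostic
  arr3 <- arr[c(1, 3), , , drop = FALSE]
  im3 <- new("IMFSet", imfs = arr3, residue = matrix(0, 1, Tn),
             epochDuration = 30, params = list())
  res <- findCircadianImf(marginalSpectrum(im3))
  expect_true(is.na(res))
  expect_match(attr(res, "diagnostic"), "no IMF peak")
})
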