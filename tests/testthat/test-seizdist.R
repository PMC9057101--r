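test_that("IMF-space reconstruction is linear and exact on toys", {
  # k = 1, W = (1,1)^T, IMF row (0.3, -0.1)
  Tn <- 2
  arr <- array(0, dim = c(1, 1, Tn))
  arr[1, 1, ] <- c(0.3, -0.1)
  imfset <- new("IMFSet", imfs = arr, residue = matrix(0, 1, Tn),
                epochDuration = 30, params = list())
  rec <- reconstructImfSpace(matrix(1, 2, 1), imfset)
  expect_equal(rec$imf[[1]], rbind(c(0.3, -0.1), c(0.3, -0.1)))
  expect_equal(rec$residue, matrix(0, 2, Tn))
  # toy distance: sqrt(2 * 0.4^2)
  D <- imfSeizureDistance(rec$imf[[1]], c(0L, 1L))
  expect_equal(D[1, 2], sqrt(2 * 0.4^2), tolerance = 1e-12)
  expect_equal(D[2, 1], D[1, 2])
  expect_equal(diag(D), c(0, 0))
  # duplicating channel rows scales distances by sqrt(2)
  D2 <- imfSeizureDistance(rbind(rec$imf[[1]], rec$imf[[1]]), c(0L, 1L))
  expect_equal(D2, sqrt(2) * D, tolerance = 1e-12)
})

test_that("reconstructions sum back to W %*% H (additivity over IMFs)", {
  run <- NULL
  set.seed(5)
  H <- matrix(rnorm(3 * 256), 3)
  im <- memd(H, n_dirs = 16, seed = 1)
  W <- matrix(runif(12), 4, 3)
  rec <- reconstructImfSpace(W, im)
  total <- Reduce(`+`, rec$imf) + rec$residue
  expect_lt(max(abs(total - W %*% H)) / diff(range(W %*% H)), 1e-8)
})

test_that("temporal distance and onset-epoch bookkeeping follow the conventions", {
  st <- seizureTable(c(100, 400), n_epochs = 100)
  expect_equal(st@onsetEpochs, c(3L, 13L))  # floor(onset / 30)
  td <- temporalDistance(st)
  expect_equal(td[1, 2], 300)
  expect_equal(diag(td), c(0, 0))
  # sorted onsets: entries grow away from the diagonal along a row
  st3 <- seizureTable(c(50, 800, 2000), n_epochs = 100)
  td3 <- temporalDistance(st3)
  expect_true(all(diff(td3[1, ]) > 0))
  # out-of-range onsets refused
  expect_error(seizureTable(c(10, 4000), n_epochs = 100), "range")
  # lag pushes epochs back; underflow refused
  expect_error(imfSeizureDistance(matrix(1, 2, 10), c(0L, 5L), lag = 1),
               "out of range")
})

test_that("DTW distance has its defining invariances", {
  set.seed(3)
  a <- matrix(rnorm(10), 5, 2)
  expect_equal(dtwDistance(a, a), 0)
  # 2x time-dilated copy -> 0
  expect_equal(dtwDistance(a, a[rep(1:5, each = 2), ]), 0)
  expect_error(dtwDistance(a, matrix(1, 4, 3)), "mismatch")
  # symmetry of the dissimilarity matrix
  evs <- lapply(1:4, function(i) matrix(rnorm(12), 6, 2))
  D <- dtwDissimilarity(evs)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 4))
  expect_true(all(D >= 0))
})

test_that("DTW equals an exhaustive dynamic program on random pairs", {
  # enumerate every monotone boundary-anchored warping path
  bruteDtw <- function(a, b) {
    n <- nrow(a); m <- nrow(b)
    cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
    best <- list(total = Inf, len = NA)
    recurse <- function(i, j, tot, len) {
      tot <- tot + cost(i, j)
      if (i == n && j == m) {
        if (tot < best$total) best <<- list(total = tot, len = len)
        return(invisible())
      }
      if (i < n && j < m) recurse(i + 1, j + 1, tot, len + 1)
      if (i < n) recurse(i + 1, j, tot, len + 1)
      if (j < m) recurse(i, j + 1, tot, len + 1)
    }
    recurse(1, 1, 0, 1)
    best$total / best$len
  }
  set.seed(42)
  for (rep in 1:25) {
    a <- matrix(rnorm(2 * sample(3:6, 1)), ncol = 2)
    b <- matrix(rnorm(2 * sample(3:6, 1)), ncol = 2)
    expect_equal(dtwDistance(a, b), bruteDtw(a, b), tolerance = 1e-12)
  }
})

test_that("seizure distance stacks pass symmetry and circadian recovery", {
  run <- fixtureRun(1)
  fx <- run$fx
  st <- seizureTable(fx$seizures$onsets_s,
                     ncol(SummarizedExperiment::assay(run$bp)))
  dists <- seizureDistances(nmfW(run$fact), run$imfset, st)
  expect_true(validObject(dists))
  expect_equal(dists@labels[length(dists@labels)], "temporal")
  # circadian IMF distance should track the planted circadian-state
  # distance between seizure onsets; the fixture's circadian process is
  # 2-dimensional (two phase-shifted planted modulators), so the state
  # distance is Euclidean over both
  ci <- findCircadianImf(run$spectrum)
  expect_false(is.na(ci))
  stt <- fx$seizures$states
  planted_circ <- sqrt(outer(stt[1, ], stt[1, ], "-")^2 +
                       outer(stt[2, ], stt[2, ], "-")^2)
  ut <- upper.tri(planted_circ)
  rho <- cor(dists@D[ci, , ][ut], planted_circ[ut], method = "spearman")
  expect_gte(rho, 0.7)
  # and the ultradian IMF tracks the 2-D ultradian state distance
  pk <- run$pipeline$peaks
  ui <- which.min(abs(log(pk / 4)))
  planted_ult <- sqrt(outer(stt[3, ], stt[3, ], "-")^2 +
                      outer(stt[4, ], stt[4, ], "-")^2)
  expect_gte(cor(dists@D[ui, , ][ut], planted_ult[ut],
                 method = "spearman"), 0.7)
})
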