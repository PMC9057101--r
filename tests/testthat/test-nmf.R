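# Identifiable planted nonnegative factors: disjoint W support blocks,
# independent uniform H rows.
plantedNMF <- function(n = 30, Tn = 800, k = 4, noise = 0.005, seed = 1) {
  set.seed(seed)
  W0 <- matrix(0, n, k)
  for (j in seq_len(k)) W0[((j - 1) * 7 + 1):(j * 7), j] <- runif(7, 0.5, 1)
  H0 <- matrix(runif(k * Tn), k)
  list(W0 = W0, H0 = H0,
       X = W0 %*% H0 + abs(matrix(rnorm(n * Tn, 0, noise), n)))
}

bestCosines <- function(W0, W) {
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  vapply(seq_len(ncol(W0)), function(i)
    max(vapply(seq_len(ncol(W)), function(j) cs(W0[, i], W[, j]),
               numeric(1))), numeric(1))
}

test_that("relative error follows the mean-absolute-deviation formula", {
  expect_equal(relativeError(diag(2), diag(2)), 0)
  expect_equal(relativeError(rbind(c(1, 0), c(0, 1)),
                             rbind(c(0.5, 0), c(0, 1))), 0.125)
  # homogeneity: scaling both matrices scales the error
  set.seed(1)
  A <- matrix(runif(12), 3); B <- matrix(runif(12), 3)
  expect_equal(relativeError(3 * A, 3 * B), 3 * relativeError(A, B),
               tolerance = 1e-12)
  expect_error(relativeError(A, matrix(1, 2, 2)), "mismatch")
})

test_that("redundancy is the max absolute pairwise correlation, scale-invariant", {
  set.seed(2)
  W <- matrix(runif(40), 10)
  H <- matrix(runif(4000), 4)
  W[, 2] <- W[, 1]  # duplicated component
  expect_equal(redundancy(W[, 1:2], H[1:2, ]), 1)
  # brute-force all-pairs oracle
  brute <- function(W, H) {
    mx <- 0
    for (a in 1:(ncol(W) - 1)) for (b in (a + 1):ncol(W))
      mx <- max(mx, abs(cor(W[, a], W[, b])))
    for (a in 1:(nrow(H) - 1)) for (b in (a + 1):nrow(H))
      mx <- max(mx, abs(cor(H[a, ], H[b, ])))
    mx
  }
  W2 <- matrix(runif(40), 10); H2 <- matrix(runif(4000), 4)
  expect_equal(redundancy(W2, H2), brute(W2, H2), tolerance = 1e-12)
  # invariant to positive rescaling of a component
  W3 <- W2; W3[, 2] <- 5 * W3[, 2]
  H3 <- H2; H3[3, ] <- 0.1 * H3[3, ]
  expect_equal(redundancy(W3, H3), redundancy(W2, H2), tolerance = 1e-12)
  expect_message(v <- redundancy(matrix(1:4, 4, 1), matrix(1:5, 1)),
                 "k = 1")
  expect_equal(v, 0)
})

test_that("NNSVD-LRC initialization recovers rank-1 exactly and is deterministic", {
  set.seed(3)
  w <- runif(12); h <- runif(60)
  X <- w %*% t(h)
  init <- nnsvdLrcInit(X, 1)
  expect_lt(relativeError(X, init$W0 %*% init$H0), 1e-8)
  init2 <- nnsvdLrcInit(X, 1)
  expect_identical(init, init2)
  expect_error(nnsvdLrcInit(X, 20), "min")
})

test_that("NNSVD-LRC start beats the median random-uniform start", {
  p <- plantedNMF(noise = 0.02, seed = 4)
  init <- nnsvdLrcInit(p$X, 3)
  err_init <- relativeError(p$X, init$W0 %*% init$H0)
  set.seed(5)
  rand_errs <- replicate(20, {
    W <- matrix(runif(nrow(p$X) * 3), ncol = 3)
    H <- matrix(runif(3 * ncol(p$X)), nrow = 3)
    relativeError(p$X, W %*% H)
  })
  expect_lte(err_init, median(rand_errs))
})

test_that("multiplicative updates are monotone, nonnegative, and recover exact low rank", {
  p <- plantedNMF(noise = 0, seed = 6)
  f <- suppressWarnings(nmfFactorize(p$X, 4, max_iter = 2000, tol = 0))
  expect_true(all(diff(f@objective) <= 1e-8 * f@objective[1]))
  expect_true(all(nmfW(f) >= 0) && all(nmfH(f) >= 0))
  # exact low rank: limited by the slow multiplicative-update tail
  expect_lt(relError(f), 1e-3)
  # planted recovery with small noise
  p2 <- plantedNMF(seed = 7)
  f2 <- suppressWarnings(nmfFactorize(p2$X, 4))
  expect_true(all(bestCosines(p2$W0, nmfW(f2)) >= 0.9))
})

test_that("rank selection follows the error threshold and redundancy rule", {
  p <- plantedNMF(seed = 8)
  f <- suppressWarnings(selectRank(p$X, 3, 6))
  expect_lt(relError(f), 0.05)
  expect_false(f@flagged)
  expect_true(all(bestCosines(p$W0, nmfW(f)) >= 0.9))
  # fallback path: demand an unattainable error threshold
  expect_message(
    ff <- suppressWarnings(selectRank(p$X, 3, 4, err_threshold = 1e-9)),
    "flagged")
  expect_true(ff@flagged)
  expect_error(selectRank(matrix(runif(20), 4, 5), 3, 10), "exceeds")
})
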