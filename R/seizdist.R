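#' @include AllClasses.R
NULL

#' Build a seizure table from onset times
#'
#' @param onsets_s seizure onset times in seconds, strictly ascending.
#' @param n_epochs number of epochs in the recording.
#' @param epoch_s epoch duration, seconds (default 30).
#' @return A \linkS4class{SeizureTable}; onset epochs are the 0-based
#'   epochs containing each onset (floor division).
#' @export
seizureTable <- function(onsets_s, n_epochs, epoch_s = 30) {
  ep <- as.integer(floor(onsets_s / epoch_s))
  if (anyDuplicated(ep))
    warning("two seizures share an epoch; their IMF distance will be zero")
  new("SeizureTable", onsets_s = as.numeric(onsets_s), onsetEpochs = ep,
      epoch_s = epoch_s, nEpochs = as.integer(n_epochs))
}

#' Read seizure annotations from CSV
#'
#' Expects columns `onset_s` (and optionally `offset_s`).
#'
#' @param path CSV file path.
#' @param n_epochs,epoch_s as in [seizureTable()].
#' @return A \linkS4class{SeizureTable}.
#' @export
readSeizureCsv <- function(path, n_epochs, epoch_s = 30) {
  df <- read.csv(path)
  if (!"onset_s" %in% names(df)) stop("seizures.csv must contain onset_s")
  seizureTable(sort(df$onset_s), n_epochs, epoch_s)
}

#' Reconstruct each IMF in band/channel space
#'
#' `X'_IMFi = W %*% IMF_i` maps the i-th multivariate IMF back to the
#' original n-dimensional space of all channels and frequency bands; the
#' residue is reconstructed the same way. By linearity the
#' reconstructions (plus residue) sum to `W %*% H`.
#'
#' @param W n x k NMF basis matrix (or \linkS4class{NMFFactorization}).
#' @param imfset an \linkS4class{IMFSet}.
#' @return List with `imf` (list of n x T matrices, one per IMF) and
#'   `residue` (n x T).
#' @export
reconstructImfSpace <- function(W, imfset) {
  if (is(W, "NMFFactorization")) W <- nmfW(W)
  if (ncol(W) != dim(imfset@imfs)[2]) stop("shape mismatch between W and IMFs")
  M <- nImfs(imfset)
  list(imf = lapply(seq_len(M), function(i) W %*% imfset@imfs[i, , ]),
       residue = W %*% imfset@residue)
}

# Pairwise Euclidean distance between selected columns of a matrix.
columnDistance <- function(Xp, epochs0) {
  cols <- Xp[, epochs0 + 1L, drop = FALSE]
  as.matrix(stats::dist(t(cols)))
}

#' IMF seizure distance matrix
#'
#' `D_i(a, b)` is the Euclidean distance between the band/channel-space
#' IMF reconstruction at the two seizures' onset epochs (optionally
#' `lag` epochs earlier, e.g. lag 1 for the pre-ictal variant).
#'
#' @param Xp n x T reconstruction of one IMF ([reconstructImfSpace()]).
#' @param seizures a \linkS4class{SeizureTable} or 0-based epoch vector.
#' @param lag epochs to step back from each onset epoch (default 0).
#' @return S x S symmetric nonnegative matrix with zero diagonal.
#' @export
imfSeizureDistance <- function(Xp, seizures, lag = 0) {
  ep <- if (is(seizures, "SeizureTable")) seizures@onsetEpochs else
    as.integer(seizures)
  ep <- ep - as.integer(lag)
  if (any(ep < 0) || any(ep >= ncol(Xp)))
    stop("onset epoch (minus lag) out of range")
  unname(columnDistance(Xp, ep))
}

#' Temporal distance between seizures
#'
#' @param seizures a \linkS4class{SeizureTable} or numeric onset seconds.
#' @return S x S matrix of |onset(a) - onset(b)| in seconds.
#' @export
temporalDistance <- function(seizures) {
  on <- if (is(seizures, "SeizureTable")) seizures@onsets_s else
    as.numeric(seizures)
  if (length(on) < 2) stop("need at least two seizures")
  abs(outer(on, on, "-"))
}

#' Full seizure distance stack
#'
#' Builds the (M + 2) x S x S array of predictors for the dissimilarity
#' regression: one IMF distance matrix per IMF, the residue distance,
#' and the temporal distance.
#'
#' @param W NMF basis matrix or \linkS4class{NMFFactorization}.
#' @param imfset an \linkS4class{IMFSet}.
#' @param seizures a \linkS4class{SeizureTable}.
#' @param lag epochs to step back from onsets (default 0).
#' @param recon optional precomputed [reconstructImfSpace()] output.
#' @return A \linkS4class{SeizureDistanceSet}.
#' @export
seizureDistances <- function(W, imfset, seizures, lag = 0, recon = NULL) {
  if (is.null(recon)) recon <- reconstructImfSpace(W, imfset)
  M <- length(recon$imf)
  S <- length(seizures@onsets_s)
  D <- array(0, dim = c(M + 2, S, S))
  for (i in seq_len(M))
    D[i, , ] <- imfSeizureDistance(recon$imf[[i]], seizures, lag)
  D[M + 1, , ] <- imfSeizureDistance(recon$residue, seizures, lag)
  D[M + 2, , ] <- temporalDistance(seizures)
  new("SeizureDistanceSet", D = D,
      labels = c(sprintf("IMF%d", seq_len(M)), "residue", "temporal"),
      lag = as.integer(lag))
}

# DTW with symmetric steps; returns total cost and path length of the
# cost-minimizing boundary-anchored path (diagonal preferred on ties).
dtwCore <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  cost <- matrix(0, n, m)
  for (i in seq_len(n)) {
    d <- sweep(b, 2, a[i, ], "-")
    cost[i, ] <- sqrt(rowSums(d * d))
  }
  acc <- matrix(Inf, n, m)
  acc[1, 1] <- cost[1, 1]
  if (m > 1) for (j in 2:m) acc[1, j] <- acc[1, j - 1] + cost[1, j]
  if (n > 1) for (i in 2:n) {
    acc[i, 1] <- acc[i - 1, 1] + cost[i, 1]
    if (m > 1) for (j in 2:m)
      acc[i, j] <- cost[i, j] + min(acc[i - 1, j - 1], acc[i - 1, j],
                                    acc[i, j - 1])
  }
  # backtrack for path length
  i <- n; j <- m; len <- 1L
  while (i > 1 || j > 1) {
    if (i == 1) j <- j - 1
    else if (j == 1) i <- i - 1
    else {
      prev <- c(acc[i - 1, j - 1], acc[i - 1, j], acc[i, j - 1])
      step <- which.min(prev)  # diagonal preferred on ties
      if (step == 1) { i <- i - 1; j <- j - 1 }
      else if (step == 2) i <- i - 1
      else j <- j - 1
    }
    len <- len + 1L
  }
  list(total = acc[n, m], length = len)
}

#' Dynamic-time-warping distance between two multivariate sequences
#'
#' Boundary-anchored DTW with symmetric steps (diagonal, horizontal,
#' vertical), Euclidean local cost, no warping window; the dissimilarity
#' is the mean local cost along the optimal (minimum total cost) path,
#' so a sequence and its time-dilated copy are at distance zero.
#'
#' @param a,b time x feature matrices (same feature dimension).
#' @return Nonnegative scalar.
#' @export
dtwDistance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("feature-dimension mismatch")
  if (nrow(a) < 2 || nrow(b) < 2) stop("sequences need >= 2 time steps")
  r <- dtwCore(a, b)
  r$total / r$length
}

#' Seizure dissimilarity matrix by dynamic time warping
#'
#' Pairwise DTW dissimilarity between per-seizure evolution matrices
#' (time x feature trajectories through a feature space).
#'
#' @param evolutions list of time x feature matrices, one per seizure.
#' @return S x S symmetric nonnegative matrix with zero diagonal.
#' @export
dtwDissimilarity <- function(evolutions) {
  S <- length(evolutions)
  D <- matrix(0, S, S)
  for (a in seq_len(S - 1)) {
    for (b in seq(a + 1, S)) {
      D[a, b] <- D[b, a] <- dtwDistance(evolutions[[a]], evolutions[[b]])
    }
  }
  D
}
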