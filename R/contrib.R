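#' @include AllClasses.R
NULL

#' Mean and relative power per IMF dimension
#'
#' `E[i, j]` is the mean squared instantaneous amplitude of dimension j
#' of IMF i over valid epochs; `R[i, j] = E[i, j] / sum_j E[i, j]` is the
#' relative power of each dimension within the IMF. The residue is
#' appended as one extra row when `include_residue` is TRUE, so it can be
#' carried through contribution and heterogeneity summaries.
#'
#' @param imfset an \linkS4class{IMFSet}.
#' @param traces optional precomputed traces from [analyticSignal()].
#' @param include_residue append the residue as a final row
#'   (default TRUE).
#' @return List with matrices `E` and `R` ((M or M+1) x k); R rows sum
#'   to 1.
#' @export
imfPower <- function(imfset, traces = NULL, include_residue = TRUE) {
  if (is.null(traces)) traces <- hilbertTraces(imfset, include_residue)
  n_rows <- length(traces)
  k <- dim(imfset@imfs)[2]
  E <- matrix(NA_real_, n_rows, k)
  for (i in seq_len(n_rows)) {
    for (j in seq_len(k)) {
      tr <- traces[[i]][[j]]
      edge_ok <- rep(TRUE, length(tr@amplitude))
      edge <- ceiling(edgeFraction() * length(tr@amplitude))
      edge_ok[c(seq_len(edge),
                seq(length(edge_ok) - edge + 1, length(edge_ok)))] <- FALSE
      E[i, j] <- mean(tr@amplitude[edge_ok]^2)
    }
  }
  if (any(rowSums(E) == 0)) stop("an IMF has all-zero power (degenerate)")
  R <- E / rowSums(E)
  labs <- sprintf("IMF%d", seq_len(nImfs(imfset)))
  if (n_rows > nImfs(imfset)) labs <- c(labs, "residue")
  rownames(E) <- rownames(R) <- labs
  list(E = E, R = R)
}

rowIndexFrom <- function(row_index) {
  if (is(row_index, "BandPowerMatrix") || is(row_index, "SummarizedExperiment"))
    row_index <- as.data.frame(SummarizedExperiment::rowData(row_index))
  stopifnot(all(c("band", "channel") %in% names(row_index)))
  row_index
}

#' Frequency-band contribution per IMF
#'
#' Sums the W feature weights within each band (channels collapsed) to a
#' 5 x k band-weight matrix, weights it by each IMF's relative dimension
#' powers R, and normalizes to a percentage: the contribution of each
#' main frequency band to each IMF.
#'
#' @param W n x k NMF basis matrix (rows are (band, channel) pairs).
#' @param R relative power matrix from [imfPower()].
#' @param row_index data.frame with `band`/`channel` per W row, or the
#'   \linkS4class{BandPowerMatrix} itself.
#' @return Matrix (rows = IMFs (+residue), cols = bands) of percentages;
#'   rows sum to 100.
#' @export
bandContribution <- function(W, R, row_index) {
  ri <- rowIndexFrom(row_index)
  if (nrow(ri) != nrow(W)) stop("row_index does not match W")
  bands <- unique(ri$band)
  if (!all(table(ri$band) > 0)) stop("missing band in row_index")
  B <- do.call(rbind, lapply(bands, function(b)
    colSums(W[ri$band == b, , drop = FALSE])))
  rownames(B) <- bands
  contrib <- R %*% t(B)   # rows: IMFs, cols: bands
  pct <- 100 * contrib / rowSums(contrib)
  pct
}

#' Gini sparsity index
#'
#' For a nonnegative vector x sorted ascending,
#' `G(x) = 1 - 2 * sum_i (x_i / ||x||_1) * (N - i + 1/2) / N`.
#' 0 for a perfectly even vector; `1 - 1/N` for a one-hot vector.
#' Scale- and permutation-invariant.
#'
#' @param x nonnegative numeric vector, not all zero.
#' @return Scalar in [0, 1).
#' @export
#' @examples
#' giniIndex(rep(1, 10))      # 0
#' giniIndex(c(rep(0, 9), 1)) # 0.9
giniIndex <- function(x) {
  if (any(x < 0)) stop("negative entries")
  s <- sum(x)
  if (s == 0) stop("all-zero vector")
  x <- sort(x)
  N <- length(x)
  1 - 2 * sum(x / s * (N - seq_len(N) + 0.5) / N)
}

#' Channel heterogeneity of IMF contributions, per band
#'
#' The per-IMF contribution vector `C_i = sum_j R[i, j] * W[, j]` (length
#' n) is split by frequency band, and the Gini index is computed over the
#' channel entries of each band slice: one heterogeneity value per IMF
#' and band. Values near 0 mean all channels contribute evenly; values
#' near 1 mean a few channels dominate.
#'
#' @inheritParams bandContribution
#' @return Matrix (rows = IMFs (+residue), cols = bands) of Gini indices.
#' @export
channelHeterogeneity <- function(W, R, row_index) {
  ri <- rowIndexFrom(row_index)
  bands <- unique(ri$band)
  out <- matrix(NA_real_, nrow(R), length(bands),
                dimnames = list(rownames(R), bands))
  for (i in seq_len(nrow(R))) {
    Ci <- drop(W %*% R[i, ])
    for (b in seq_along(bands))
      out[i, b] <- giniIndex(Ci[ri$band == bands[b]])
  }
  out
}
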