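#' @include AllClasses.R
NULL

# Frequency-domain analytic signal (Hilbert transform).
analyticVector <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Analytic signal of an epoch series
#'
#' Builds the analytic signal via the frequency-domain Hilbert transform
#' and returns instantaneous amplitude, unwrapped phase, and
#' instantaneous frequency (central differences of the phase, converted
#' to cycles/day). The first and last 3% of samples are masked invalid
#' (edge effects of the discrete transform), as are samples with
#' non-finite or non-positive instantaneous frequency and zero
#' amplitude.
#'
#' @param x real numeric vector (one IMF dimension over epochs).
#' @param epoch_s seconds per sample (default 30).
#' @return An \linkS4class{AnalyticTrace}.
#' @export
analyticSignal <- function(x, epoch_s = 30) {
  if (!all(is.finite(x))) stop("non-finite input")
  n <- length(x)
  if (n < 16) stop("series too short (need >= 16 samples)")
  v <- analyticVector(x)
  amp <- Mod(v)
  ph <- unwrapPhase(Arg(v))
  dphi <- numeric(n)
  dphi[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) / 2
  dphi[1] <- ph[2] - ph[1]
  dphi[n] <- ph[n] - ph[n - 1]
  f <- dphi / (2 * pi) * (86400 / epoch_s)   # cycles/day
  edge <- ceiling(edgeFraction() * n)
  valid <- rep(TRUE, n)
  valid[seq_len(edge)] <- FALSE
  valid[seq(n - edge + 1, n)] <- FALSE
  valid <- valid & is.finite(f) & f > 0 & amp > 0
  new("AnalyticTrace", amplitude = amp, phase = ph, instFreq = f,
      validMask = valid, epochDuration = epoch_s)
}

# All analytic traces of an IMF set (+ optionally residue), as a list
# indexed [[imf]][[dimension]].
hilbertTraces <- function(imfset, include_residue = FALSE) {
  M <- nImfs(imfset)
  k <- dim(imfset@imfs)[2]
  out <- lapply(seq_len(M), function(i)
    lapply(seq_len(k), function(j)
      analyticSignal(imfset@imfs[i, j, ], imfset@epochDuration)))
  if (include_residue)
    out[[M + 1]] <- lapply(seq_len(k), function(j)
      analyticSignal(imfset@residue[j, ], imfset@epochDuration))
  out
}

# Log-spaced frequency bin edges in cycles/day.
spectralBins <- function(n_epochs, epoch_s, n_bins_per_decade = 48) {
  fmin <- 2 / (n_epochs * epoch_s / 86400)
  fmax <- 86400 / (2 * epoch_s)
  lo <- log10(fmin); hi <- log10(fmax)
  edges <- 10^seq(floor(lo * n_bins_per_decade) / n_bins_per_decade,
                  ceiling(hi * n_bins_per_decade) / n_bins_per_decade,
                  by = 1 / n_bins_per_decade)
  edges
}

#' Hilbert-Huang marginal spectrum of an IMF set
#'
#' For each IMF, squared instantaneous amplitudes (averaged across the k
#' dimensions) are accumulated into the log-spaced frequency bin
#' containing each sample's instantaneous frequency; the time integral is
#' discretised as a sum over epochs. Binning partitions the valid
#' samples, so each IMF row sums to its total valid energy.
#'
#' @param imfset an \linkS4class{IMFSet}.
#' @param n_bins_per_decade bins per frequency decade (default 48).
#' @param traces optional precomputed [analyticSignal()] traces.
#' @return A \linkS4class{MarginalSpectrum}.
#' @export
marginalSpectrum <- function(imfset, n_bins_per_decade = 48, traces = NULL) {
  M <- nImfs(imfset)
  k <- dim(imfset@imfs)[2]
  Tn <- dim(imfset@imfs)[3]
  if (is.null(traces)) traces <- hilbertTraces(imfset)
  edges <- spectralBins(Tn, imfset@epochDuration, n_bins_per_decade)
  nb <- length(edges) - 1
  dens <- matrix(0, M, nb)
  for (i in seq_len(M)) {
    for (j in seq_len(k)) {
      tr <- traces[[i]][[j]]
      f <- tr@instFreq[tr@validMask]
      a2 <- tr@amplitude[tr@validMask]^2 / k
      f <- pmin(pmax(f, edges[1]), edges[nb + 1] * (1 - 1e-12))
      bin <- findInterval(f, edges, rightmost.closed = TRUE)
      acc <- tapply(a2, bin, sum)
      dens[i, as.integer(names(acc))] <- dens[i, as.integer(names(acc))] + acc
    }
  }
  rownames(dens) <- sprintf("IMF%d", seq_len(M))
  new("MarginalSpectrum", binEdges = edges, density = dens,
      labels = rownames(dens), epochDuration = imfset@epochDuration,
      nEpochs = as.integer(Tn))
}

#' Total marginal spectrum across IMFs
#'
#' @param spectrum a \linkS4class{MarginalSpectrum}.
#' @return Numeric vector: per-bin energy summed over IMFs.
#' @export
totalSpectrum <- function(spectrum) colSums(spectrum@density)

#' Peak fluctuation frequency of an IMF
#'
#' The geometric centre of the marginal-spectrum bin with the highest
#' energy; ties are broken toward the lower frequency (with a warning).
#'
#' @param spectrum a \linkS4class{MarginalSpectrum}.
#' @param imf_index which IMF row.
#' @return Peak frequency in cycles/day.
#' @export
peakFrequency <- function(spectrum, imf_index) {
  d <- spectrum@density[imf_index, ]
  if (all(d == 0)) stop("all-zero marginal spectrum")
  mx <- max(d)
  hits <- which(d >= mx - 1e-300 & d == mx)
  if (length(hits) > 1)
    warning("tied spectral peaks; returning the lower frequency")
  b <- hits[1]
  sqrt(spectrum@binEdges[b] * spectrum@binEdges[b + 1])
}

#' Find the circadian IMF
#'
#' Returns the index of the IMF whose peak fluctuation frequency lies in
#' the tolerance band around 1 cycle/day (default: peak period within
#' [0.8, 1.25] days). When several IMFs qualify, the one with the larger
#' total marginal power wins. Absence is a valid result (NA with a
#' diagnostic attribute).
#'
#' @param spectrum a \linkS4class{MarginalSpectrum}.
#' @param band period tolerance band in days (default c(0.8, 1.25)).
#' @return Integer IMF index, or NA if no IMF peaks in-band.
#' @export
findCircadianImf <- function(spectrum, band = c(0.8, 1.25)) {
  M <- nrow(spectrum@density)
  peaks <- vapply(seq_len(M), function(i)
    suppressWarnings(peakFrequency(spectrum, i)), numeric(1))
  periods <- 1 / peaks
  cand <- which(periods >= band[1] & periods <= band[2])
  if (!length(cand)) {
    out <- NA_integer_
    attr(out, "diagnostic") <- sprintf(
      "no IMF peak period in [%.3g, %.3g] days; nearest peak period %.3g days",
      band[1], band[2], periods[which.min(abs(log(periods)))])
    return(out)
  }
  pow <- rowSums(spectrum@density)[cand]
  cand[which.max(pow)]
}
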