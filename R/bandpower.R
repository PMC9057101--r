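#' Divide a recording into non-overlapping epochs
#'
#' Splits a multichannel signal into contiguous, non-overlapping epochs of
#' `epoch_s` seconds; a trailing partial epoch is discarded. Epoch `t`
#' (0-based) covers samples `[t*fs*epoch_s, (t+1)*fs*epoch_s)`.
#'
#' @param signal numeric vector, or channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param epoch_s epoch duration, seconds (default 30).
#' @return List of channels x (fs*epoch_s) matrices, one per epoch.
#' @export
#' @examples
#' e <- epochSignal(matrix(rnorm(2 * 3000), 2), fs = 50, epoch_s = 30)
#' length(e)  # 2 epochs
epochSignal <- function(signal, fs, epoch_s = 30) {
  stopifnot(fs > 0, epoch_s > 0)
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  len <- round(fs * epoch_s)
  n <- ncol(signal)
  if (n < len) stop("recording shorter than one epoch")
  nT <- n %/% len
  lapply(seq_len(nT) - 1L, function(t)
    signal[, (t * len + 1):((t + 1) * len), drop = FALSE])
}

# Welch PSD of one segment-matrix (samples x segments), one-sided density:
# integrates to the signal variance. Hamming taper.
welchPSD <- function(segs, fs) {
  N <- nrow(segs)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(N) - 1) / (N - 1))
  scale <- 1 / (fs * sum(w^2))
  ft <- mvfft(segs * w)
  nf <- N %/% 2 + 1
  psd <- (Mod(ft[seq_len(nf), , drop = FALSE])^2) * scale
  mult <- rep(2, nf)
  mult[1] <- 1
  if (N %% 2 == 0) mult[nf] <- 1
  psd * mult
}

#' Welch band power of a single epoch
#'
#' Estimates band power for each frequency band by Welch's method: the
#' epoch is divided into non-overlapping `seg_s`-second Hamming-tapered
#' segments, the one-sided periodogram of each segment is computed, band
#' power is the PSD integrated over `[lo, hi)` and averaged over segments.
#'
#' @param epoch numeric vector (one channel's epoch samples).
#' @param fs sampling rate, Hz.
#' @param bands data.frame as [defaultBands()].
#' @param seg_s Welch segment length, seconds (default 3).
#' @return Named numeric vector of band powers (signal-variance units).
#' @export
welchBandPower <- function(epoch, fs, bands = defaultBands(), seg_s = 3) {
  checkBands(bands, fs)
  N <- round(fs * seg_s)
  if (length(epoch) %% N != 0)
    stop("epoch length must be a multiple of the segment length")
  nseg <- length(epoch) %/% N
  segs <- matrix(epoch, nrow = N, ncol = nseg)
  psd <- welchPSD(segs, fs)
  df <- fs / N
  freqs <- (seq_len(nrow(psd)) - 1) * df
  pw <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- freqs >= bands$lo[b] & freqs < bands$hi[b]
    mean(colSums(psd[sel, , drop = FALSE])) * df
  }, numeric(1))
  names(pw) <- bands$name
  pw
}

#' Welch band-power time series for a whole recording
#'
#' Computes the 5 x #channels x #epochs raw band-power array for a
#' multichannel recording, processing each channel in segment-matrix
#' chunks so multi-day recordings stay within memory.
#'
#' @param signals channels x samples matrix, or a single-channel
#'   numeric vector.
#' @param fs sampling rate, Hz.
#' @param bands data.frame as [defaultBands()].
#' @param epoch_s epoch duration, seconds.
#' @param seg_s Welch segment length, seconds.
#' @return Numeric array #bands x #channels x #epochs.
#' @export
welchPowerSeries <- function(signals, fs, bands = defaultBands(),
                             epoch_s = 30, seg_s = 3) {
  checkBands(bands, fs)
  vec_in <- is.vector(signals)
  C <- if (vec_in) 1L else nrow(signals)
  n_samp <- if (vec_in) length(signals) else ncol(signals)
  N <- round(fs * seg_s)
  segs_per_epoch <- round(epoch_s / seg_s)
  if (n_samp < N * segs_per_epoch)
    stop("recording shorter than one epoch")
  nT <- n_samp %/% (N * segs_per_epoch)
  nb <- nrow(bands)
  freqs <- (seq_len(N %/% 2 + 1) - 1) * (fs / N)
  binsel <- matrix(0L, nb, length(freqs))
  for (b in seq_len(nb))
    binsel[b, freqs >= bands$lo[b] & freqs < bands$hi[b]] <- 1L
  out <- array(NA_real_, dim = c(nb, C, nT),
               dimnames = list(bands$name,
                               if (vec_in) NULL else rownames(signals),
                               NULL))
  df <- fs / N
  chunk_epochs <- 1024L
  for (ch in seq_len(C)) {
    x <- if (vec_in) signals else signals[ch, ]
    for (start in seq(1L, nT, by = chunk_epochs)) {
      ep <- start:min(start + chunk_epochs - 1L, nT)
      i0 <- (ep[1] - 1L) * N * segs_per_epoch + 1L
      i1 <- ep[length(ep)] * N * segs_per_epoch
      segs <- matrix(x[i0:i1], nrow = N)
      psd <- welchPSD(segs, fs)
      for (b in seq_len(nb)) {
        bp <- colSums(psd[binsel[b, ] == 1L, , drop = FALSE]) * df
        out[b, ch, ep] <- colMeans(matrix(bp, nrow = segs_per_epoch))
      }
    }
  }
  out
}

#' Normalize raw band powers and stack into the data matrix X
#'
#' Per band: natural log (power floored at 1e-12), z-scoring with the
#' mean/SD pooled over that band's channels x epochs, then the logistic
#' squashing S(x) = 1/(1+exp(-x)). Band blocks are stacked row-wise in
#' band-major order (all channels of band 1, then band 2, ...).
#'
#' @param raw_power array #bands x #channels x #epochs of nonnegative
#'   powers, as from [welchPowerSeries()].
#' @param bands band definitions (names used for the row index).
#' @param channels optional channel names.
#' @param epoch_s epoch duration, seconds.
#' @return A \linkS4class{BandPowerMatrix}.
#' @export
normalizeAndStack <- function(raw_power, bands = defaultBands(),
                              channels = NULL, epoch_s = 30) {
  stopifnot(length(dim(raw_power)) == 3)
  if (any(raw_power < 0)) stop("raw powers must be nonnegative")
  nb <- dim(raw_power)[1]
  C <- dim(raw_power)[2]
  nT <- dim(raw_power)[3]
  if (nb != nrow(bands)) stop("raw_power bands disagree with band table")
  if (is.null(channels)) {
    channels <- dimnames(raw_power)[[2]]
    if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(C))
  }
  X <- matrix(NA_real_, nrow = nb * C, ncol = nT)
  mus <- sds <- numeric(nb)
  for (b in seq_len(nb)) {
    v <- log(pmax(raw_power[b, , , drop = FALSE], 1e-12))
    dim(v) <- c(C, nT)
    mus[b] <- mean(v)
    sds[b] <- sd(as.vector(v))
    if (!is.finite(sds[b]) || sds[b] == 0)
      stop(sprintf("degenerate input: zero pooled SD in band '%s'",
                   bands$name[b]))
    z <- (v - mus[b]) / sds[b]
    X[(b - 1) * C + seq_len(C), ] <- 1 / (1 + exp(-z))
  }
  rd <- S4Vectors::DataFrame(
    band = rep(bands$name, each = C),
    channel = rep(channels, nb)
  )
  rownames(X) <- paste(rd$band, rd$channel, sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(X = X), rowData = rd,
    metadata = list(epoch_s = epoch_s,
                    normalization = list(bands = bands$name,
                                         log_mean = mus, log_sd = sds))
  )
  new("BandPowerMatrix", se)
}

#' Band-power data matrix from a recording
#'
#' End-to-end preprocessing: Welch band power per 30 s epoch, log,
#' band-wise standardisation, sigmoid squashing, band-major stacking.
#' Seizure epochs are retained by default; `exclude_epochs` (0-based)
#' drops the given epochs before normalization for sensitivity analyses.
#'
#' @param x a \linkS4class{SyntheticRecording} or channels x samples
#'   matrix.
#' @param fs sampling rate (ignored when `x` is a recording object).
#' @param bands band definitions.
#' @param epoch_s epoch duration, seconds.
#' @param seg_s Welch segment length, seconds.
#' @param exclude_epochs optional integer vector of 0-based epochs to
#'   drop.
#' @return A \linkS4class{BandPowerMatrix}.
#' @export
computeBandPower <- function(x, fs = NULL, bands = defaultBands(),
                             epoch_s = 30, seg_s = 3,
                             exclude_epochs = NULL) {
  if (is(x, "SyntheticRecording")) {
    signals <- x@signals
    fs <- x@fs
    channels <- x@channelNames
  } else {
    signals <- x
    channels <- rownames(x)
    if (is.null(fs)) stop("fs required for a plain signal matrix")
  }
  raw <- welchPowerSeries(signals, fs, bands, epoch_s, seg_s)
  kept <- seq_len(dim(raw)[3])
  if (!is.null(exclude_epochs)) {
    kept <- setdiff(kept, exclude_epochs + 1L)
    raw <- raw[, , kept, drop = FALSE]
  }
  bp <- normalizeAndStack(raw, bands, channels, epoch_s)
  S4Vectors::metadata(bp)$kept_epochs <- kept - 1L
  bp
}
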