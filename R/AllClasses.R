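#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' BandPowerMatrix: the normalized nonnegative band-power data matrix
#'
#' A \linkS4class{SummarizedExperiment} holding the n x T data matrix X of
#' log-transformed, band-wise standardised, sigmoid-squashed Welch band
#' powers. Rows are (band, channel) pairs in band-major order (all delta
#' channels, then all theta channels, ...); columns are 30 s epochs. The
#' single assay is named `"X"`, row metadata carries `band` and `channel`,
#' and `metadata()` records the epoch duration and the per-band
#' normalization constants.
#'
#' @seealso [normalizeAndStack()], [computeBandPower()]
#' @export
setClass("BandPowerMatrix", contains = "SummarizedExperiment")

setValidity("BandPowerMatrix", function(object) {
  msg <- NULL
  a <- SummarizedExperiment::assay(object)
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("band", "channel") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'band' and 'channel'")
  else {
    nb <- length(unique(rd$band))
    nc <- length(unique(rd$channel))
    if (nrow(a) != nb * nc)
      msg <- c(msg, "n must equal #bands x #channels")
  }
  if (length(a) && (min(a) < 0 || max(a) > 1))
    msg <- c(msg, "entries must lie in [0, 1]")
  if (is.null(S4Vectors::metadata(object)$epoch_s))
    msg <- c(msg, "metadata()$epoch_s missing")
  if (is.null(msg)) TRUE else msg
})

#' NMFFactorization: result of nonnegative matrix factorization
#'
#' Holds the nonnegative factors W (n x k basis vectors / feature weights)
#' and H (k x T expression coefficient time series), the rank k, the
#' relative reconstruction error (mean absolute elementwise deviation),
#' and the redundancy index c (largest absolute Pearson correlation among
#' W columns or H rows).
#'
#' @slot W nonnegative basis matrix, n x k.
#' @slot H nonnegative coefficient matrix, k x T.
#' @slot k integer rank.
#' @slot relError mean absolute reconstruction error.
#' @slot redundancy max absolute inter-component correlation, in [0, 1].
#' @slot converged logical; FALSE when the update loop hit its cap.
#' @slot flagged logical; TRUE when rank selection fell back to the
#'   smallest-error rank because no rank met the error threshold.
#' @slot objective numeric vector of Frobenius objective values per sweep.
#' @export
setClass("NMFFactorization", representation(
  W = "matrix", H = "matrix", k = "integer",
  relError = "numeric", redundancy = "numeric",
  converged = "logical", flagged = "logical", objective = "numeric"
))

setValidity("NMFFactorization", function(object) {
  msg <- NULL
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "W and H must be nonnegative")
  if (ncol(object@W) != object@k || nrow(object@H) != object@k)
    msg <- c(msg, "factor dimensions disagree with k")
  if (object@relError < 0) msg <- c(msg, "relError must be >= 0")
  if (object@redundancy < -1e-12 || object@redundancy > 1 + 1e-12)
    msg <- c(msg, "redundancy must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' IMFSet: mode-aligned intrinsic mode functions plus residue
#'
#' Output of [memd()]: an M x k x T array of IMFs (timescale index i,
#' fastest to slowest; dimension j; epoch t) and a k x T residue, such
#' that for every dimension j the IMFs and residue sum back to the input
#' signal.
#'
#' @slot imfs numeric array M x k x T.
#' @slot residue numeric matrix k x T.
#' @slot epochDuration epoch length in seconds.
#' @slot params list of decomposition parameters (directions, sift
#'   settings, seed).
#' @export
setClass("IMFSet", representation(
  imfs = "array", residue = "matrix",
  epochDuration = "numeric", params = "list"
))

setValidity("IMFSet", function(object) {
  msg <- NULL
  d <- dim(object@imfs)
  if (length(d) != 3) msg <- c(msg, "imfs must be a 3-d array (M x k x T)")
  else {
    if (d[2] != nrow(object@residue) || d[3] != ncol(object@residue))
      msg <- c(msg, "residue dimensions disagree with imfs")
  }
  if (object@epochDuration <= 0) msg <- c(msg, "epochDuration must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' AnalyticTrace: instantaneous amplitude, phase and frequency
#'
#' Result of [analyticSignal()] for one univariate epoch series:
#' instantaneous amplitude (>= 0), unwrapped phase (radians) and
#' instantaneous frequency in cycles/day, with a validity mask excluding
#' edge samples and non-finite or non-positive frequencies.
#'
#' @slot amplitude numeric vector, >= 0.
#' @slot phase unwrapped phase, radians.
#' @slot instFreq instantaneous frequency, cycles/day.
#' @slot validMask logical vector.
#' @slot epochDuration seconds per sample.
#' @export
setClass("AnalyticTrace", representation(
  amplitude = "numeric", phase = "numeric", instFreq = "numeric",
  validMask = "logical", epochDuration = "numeric"
))

#' MarginalSpectrum: Hilbert-Huang energy over frequency
#'
#' Per-IMF marginal Hilbert-Huang spectra on a log-spaced cycles/day axis:
#' the time-integrated (discretised) energy density, averaged across the
#' k dimensions of each IMF, plus the across-IMF total.
#'
#' @slot binEdges frequency bin edges, cycles/day (left-closed).
#' @slot density M x nbins matrix of energy per bin, one row per IMF.
#' @slot labels row labels.
#' @slot epochDuration seconds per epoch.
#' @slot nEpochs number of epochs the spectra integrate over.
#' @export
setClass("MarginalSpectrum", representation(
  binEdges = "numeric", density = "matrix", labels = "character",
  epochDuration = "numeric", nEpochs = "integer"
))

setValidity("MarginalSpectrum", function(object) {
  msg <- NULL
  if (any(object@density < 0)) msg <- c(msg, "densities must be >= 0")
  if (ncol(object@density) != length(object@binEdges) - 1)
    msg <- c(msg, "density columns must match bin count")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' SeizureTable: seizure onsets mapped to epochs
#'
#' @slot onsets_s seizure onset times in seconds, strictly ascending.
#' @slot onsetEpochs 0-based epoch index containing each onset.
#' @slot epoch_s epoch duration in seconds.
#' @slot nEpochs total epochs available (onsets must fall inside).
#' @export
setClass("SeizureTable", representation(
  onsets_s = "numeric", onsetEpochs = "integer",
  epoch_s = "numeric", nEpochs = "integer"
))

setValidity("SeizureTable", function(object) {
  msg <- NULL
  if (is.unsorted(object@onsets_s, strictly = TRUE))
    msg <- c(msg, "onsets must be strictly increasing")
  if (any(object@onsetEpochs < 0) || any(object@onsetEpochs >= object@nEpochs))
    msg <- c(msg, "onset epochs out of recording range")
  if (!identical(object@onsetEpochs,
                 as.integer(floor(object@onsets_s / object@epoch_s))))
    msg <- c(msg, "onsetEpochs must equal floor(onsets_s / epoch_s)")
  if (is.null(msg)) TRUE else msg
})

#' SeizureDistanceSet: per-IMF, residue and temporal seizure distances
#'
#' An (M + 2) x S x S array: one S x S distance matrix per IMF
#' (Euclidean distance between the band/channel-space reconstructions at
#' the two onset epochs), one for the residue, and the temporal distance
#' (|onset difference| in seconds). Each slice is symmetric, nonnegative,
#' with zero diagonal.
#'
#' @slot D numeric array (M + 2) x S x S.
#' @slot labels slice labels (IMF1..IMFM, residue, temporal).
#' @slot lag epochs subtracted from each onset epoch (0 = onset epoch,
#'   1 = pre-ictal variant).
#' @export
setClass("SeizureDistanceSet", representation(
  D = "array", labels = "character", lag = "integer"
))

setValidity("SeizureDistanceSet", function(object) {
  msg <- NULL
  d <- dim(object@D)
  if (length(d) != 3 || d[2] != d[3])
    msg <- c(msg, "D must be (M+2) x S x S")
  if (length(object@labels) != d[1])
    msg <- c(msg, "labels must match slice count")
  for (i in seq_len(d[1])) {
    s <- object@D[i, , ]
    if (max(abs(s - t(s))) > 1e-8 || any(diag(s) != 0) || min(s) < 0) {
      msg <- c(msg, sprintf("slice %d is not a valid distance matrix", i))
      break
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' RegressionDataset: vectorized, standardized distances for regression
#'
#' Upper-triangle entries of the seizure dissimilarity matrix (response)
#' and of each distance slice (predictors), standardized to mean 0, SD 1.
#' Constant predictor columns are dropped with a warning; a constant
#' response marks the dataset degenerate.
#'
#' @slot y standardized response, length S(S-1)/2.
#' @slot Z standardized predictor matrix.
#' @slot labels retained predictor labels.
#' @slot dropped labels of constant predictors that were dropped.
#' @slot pairs two-column matrix of seizure indices per observation.
#' @slot degenerate TRUE when the response was constant.
#' @export
setClass("RegressionDataset", representation(
  y = "numeric", Z = "matrix", labels = "character",
  dropped = "character", pairs = "matrix", degenerate = "logical"
))

#' RegressionResult: LASSO selection, OLS refit, permutation p-values
#'
#' @slot lambda selected LASSO penalty.
#' @slot beta nonnegative LASSO coefficients at the selected penalty.
#' @slot selected labels of predictors with positive LASSO coefficients.
#' @slot coefficients data.frame of OLS estimates and 95% CIs
#'   (standardized scale) for the selected predictors.
#' @slot adjR2 adjusted R-squared of the OLS refit (0 when nothing was
#'   selected).
#' @slot pRandomTimes permutation p-value, random onset times null.
#' @slot pShuffledOrder permutation p-value, shuffled seizure order null.
#' @slot nObs number of seizure-pair observations.
#' @slot flags character notes (e.g. "empty-selection", "degenerate").
#' @export
setClass("RegressionResult", representation(
  lambda = "numeric", beta = "numeric", selected = "character",
  coefficients = "data.frame", adjR2 = "numeric",
  pRandomTimes = "numeric", pShuffledOrder = "numeric",
  nObs = "integer", flags = "character"
))

#' ModulatorSpec: a planted multiplicative band-power modulator
#'
#' Defines one latent rhythm for the synthetic-data generator: a
#' sinusoidal modulation of per-band log power at a given period, with a
#' (bands x channels) loading matrix controlling where it acts.
#'
#' @slot period period in days (> 0).
#' @slot amplitude dimensionless amplitude (>= 0) of the log-envelope
#'   sinusoid.
#' @slot phase phase in radians, [0, 2 pi).
#' @slot loading 5 x #channels matrix of weights in [0, 1].
#' @slot jitter logical; TRUE adds a +/-10% slow random-walk period
#'   jitter to exercise nonstationarity.
#' @export
setClass("ModulatorSpec", representation(
  period = "numeric", amplitude = "numeric", phase = "numeric",
  loading = "matrix", jitter = "logical"
))

setValidity("ModulatorSpec", function(object) {
  msg <- NULL
  if (object@period <= 0) msg <- c(msg, "period must be > 0")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@phase < 0 || object@phase >= 2 * pi)
    msg <- c(msg, "phase must lie in [0, 2*pi)")
  if (any(object@loading < 0) || any(object@loading > 1))
    msg <- c(msg, "loading entries must lie in [0, 1]")
  if (nrow(object@loading) != 5)
    msg <- c(msg, "loading must have 5 rows (bands)")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticRecording: generated multichannel recording with ground truth
#'
#' @slot signals channels x samples matrix (arbitrary units).
#' @slot fs sampling rate, Hz.
#' @slot channelNames channel identifiers.
#' @slot epoch_s epoch duration the truth series are tabulated on.
#' @slot seizureOnsets onset times in seconds (ascending), possibly empty.
#' @slot seizureEvolutions list of time x feature matrices per seizure.
#' @slot truth list: modulator specs, latent modulator state time series
#'   at epoch resolution, planted dissimilarity and weights, seed.
#' @export
setClass("SyntheticRecording", representation(
  signals = "matrix", fs = "numeric", channelNames = "character",
  epoch_s = "numeric", seizureOnsets = "numeric",
  seizureEvolutions = "list", truth = "list"
))

setValidity("SyntheticRecording", function(object) {
  msg <- NULL
  if (length(object@seizureOnsets) != length(object@seizureEvolutions))
    msg <- c(msg, "#onsets must equal #evolutions")
  if (length(object@seizureOnsets) &&
      is.unsorted(object@seizureOnsets, strictly = TRUE))
    msg <- c(msg, "seizure onsets must be strictly increasing")
  dur <- ncol(object@signals) / object@fs
  if (length(object@seizureOnsets) &&
      (min(object@seizureOnsets) < 0 || max(object@seizureOnsets) >= dur))
    msg <- c(msg, "seizure onsets must fall inside the recording")
  if (object@fs <= 160)
    msg <- c(msg, "fs must exceed 160 Hz so the gamma band exists")
  if (is.null(msg)) TRUE else msg
})
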