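#' @include AllClasses.R
NULL

#' Accessors for seizmod classes
#'
#' Small accessor generics: `nmfW()`/`nmfH()` return the NMF factors,
#' `nmfRank()` the rank, `relError()` the mean absolute reconstruction
#' error, `redundancyIndex()` the max absolute inter-component
#' correlation, `imfArray()`/`imfResidue()` the IMF stack and residue,
#' `nImfs()` the number of IMFs, `epochDuration()` the epoch length in
#' seconds, `adjustedR2()` the adjusted R-squared of a regression result.
#'
#' @param x a seizmod object.
#' @return The slot value.
#' @name accessors
#' @aliases nmfW nmfH nmfRank relError redundancyIndex imfArray
#'   imfResidue nImfs epochDuration adjustedR2
NULL

#' @rdname accessors
#' @export
setGeneric("nmfW", function(x) standardGeneric("nmfW"))
#' @rdname accessors
#' @export
setGeneric("nmfH", function(x) standardGeneric("nmfH"))
#' @rdname accessors
#' @export
setGeneric("nmfRank", function(x) standardGeneric("nmfRank"))
#' @rdname accessors
#' @export
setGeneric("relError", function(x) standardGeneric("relError"))
#' @rdname accessors
#' @export
setGeneric("redundancyIndex", function(x) standardGeneric("redundancyIndex"))
#' @rdname accessors
#' @export
setGeneric("imfArray", function(x) standardGeneric("imfArray"))
#' @rdname accessors
#' @export
setGeneric("imfResidue", function(x) standardGeneric("imfResidue"))
#' @rdname accessors
#' @export
setGeneric("nImfs", function(x) standardGeneric("nImfs"))
#' @rdname accessors
#' @export
setGeneric("epochDuration", function(x) standardGeneric("epochDuration"))
#' @rdname accessors
#' @export
setGeneric("adjustedR2", function(x) standardGeneric("adjustedR2"))

#' @rdname accessors
setMethod("nmfW", "NMFFactorization", function(x) x@W)
#' @rdname accessors
setMethod("nmfH", "NMFFactorization", function(x) x@H)
#' @rdname accessors
setMethod("nmfRank", "NMFFactorization", function(x) x@k)
#' @rdname accessors
setMethod("relError", "NMFFactorization", function(x) x@relError)
#' @rdname accessors
setMethod("redundancyIndex", "NMFFactorization", function(x) x@redundancy)
#' @rdname accessors
setMethod("imfArray", "IMFSet", function(x) x@imfs)
#' @rdname accessors
setMethod("imfResidue", "IMFSet", function(x) x@residue)
#' @rdname accessors
setMethod("nImfs", "IMFSet", function(x) dim(x@imfs)[1])
#' @rdname accessors
setMethod("epochDuration", "IMFSet", function(x) x@epochDuration)
#' @rdname accessors
setMethod("epochDuration", "BandPowerMatrix",
          function(x) S4Vectors::metadata(x)$epoch_s)
#' @rdname accessors
setMethod("adjustedR2", "RegressionResult", function(x) x@adjR2)

setMethod("show", "NMFFactorization", function(object) {
  cat(sprintf(
    "NMFFactorization: k = %d, n = %d, T = %d\n  rel. error = %.4g, redundancy c = %.4g%s%s\n",
    object@k, nrow(object@W), ncol(object@H),
    object@relError, object@redundancy,
    if (!object@converged) " (update cap reached)" else "",
    if (object@flagged) " [no rank met the error threshold]" else ""))
})

setMethod("show", "IMFSet", function(object) {
  d <- dim(object@imfs)
  cat(sprintf(
    "IMFSet: %d IMFs x %d dimensions x %d epochs (epoch = %gs)\n",
    d[1], d[2], d[3], object@epochDuration))
})

setMethod("show", "MarginalSpectrum", function(object) {
  cat(sprintf(
    "MarginalSpectrum: %d IMFs, %d log-spaced bins spanning %.3g-%.3g cycles/day\n",
    nrow(object@density), ncol(object@density),
    min(object@binEdges), max(object@binEdges)))
})

setMethod("show", "SeizureDistanceSet", function(object) {
  d <- dim(object@D)
  cat(sprintf("SeizureDistanceSet: %d slices (%s...) x %d seizures, lag %d\n",
              d[1], paste(head(object@labels, 3), collapse = ", "),
              d[2], object@lag))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf(
    "RegressionResult: %d obs, lambda = %.4g, adj. R^2 = %.4f\n",
    object@nObs, object@lambda, object@adjR2))
  if (length(object@selected))
    cat("  selected:", paste(object@selected, collapse = ", "), "\n")
  else cat("  selected: (none)\n")
  if (length(object@pRandomTimes))
    cat(sprintf("  p (random onset times) = %.4g\n", object@pRandomTimes))
  if (length(object@pShuffledOrder))
    cat(sprintf("  p (shuffled seizure order) = %.4g\n", object@pShuffledOrder))
})

setMethod("show", "SyntheticRecording", function(object) {
  cat(sprintf(
    "SyntheticRecording: %d channels x %d samples @ %g Hz (%.2f days), %d seizures\n",
    nrow(object@signals), ncol(object@signals), object@fs,
    ncol(object@signals) / object@fs / 86400, length(object@seizureOnsets)))
})
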