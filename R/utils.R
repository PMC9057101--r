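#' Canonical EEG frequency bands
#'
#' The five main iEEG frequency bands used throughout the package:
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30 and gamma 30-80 Hz.
#'
#' @return A data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' defaultBands()
defaultBands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(1, 4, 8, 13, 30),
    hi = c(4, 8, 13, 30, 80),
    stringsAsFactors = FALSE
  )
}

checkBands <- function(bands, fs) {
  stopifnot(is.data.frame(bands), all(c("name", "lo", "hi") %in% names(bands)))
  if (any(bands$lo <= 0) || any(bands$lo >= bands$hi))
    stop("band edges must satisfy 0 < lo < hi")
  bad <- bands$hi > fs / 2
  if (any(bad))
    stop(sprintf("band '%s' upper edge %.1f Hz exceeds Nyquist (%.1f Hz)",
                 bands$name[which(bad)[1]], bands$hi[which(bad)[1]], fs / 2))
  invisible(bands)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals
#' do not disturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Fixed affine map modulo a 31-bit prime, so partial reruns of the
#' pipeline reuse exactly the per-stage streams of a full run.
#'
#' @param seed master integer seed.
#' @param offset stage offset.
#' @return An integer seed below 2^31.
#' @export
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * offset) %% 2147483629)
}

# Unwrap a wrapped phase sequence (radians).
unwrapPhase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# Mean oscillation period of a vector in samples, from zero crossings.
meanZeroCrossPeriod <- function(x) {
  s <- sign(x)
  s[s == 0] <- 1
  nzc <- sum(diff(s) != 0)
  if (nzc == 0) return(NA_real_)
  2 * length(x) / nzc
}

# Fraction of samples masked at each end of an epoch series before
# instantaneous quantities are trusted; sized to cover the discrete
# Hilbert transform's start-edge transient at the slowest resolvable
# cycles.
edgeFraction <- function() 0.03

# Guarded Pearson correlation matrix max |off-diagonal| entry.
maxAbsCor <- function(m) {
  if (ncol(m) < 2) return(0)
  cc <- suppressWarnings(cor(m))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  max(abs(cc))
}
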