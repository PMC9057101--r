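#' @include AllClasses.R
NULL

bpAssay <- function(X) {
  if (is(X, "BandPowerMatrix") || is(X, "SummarizedExperiment"))
    SummarizedExperiment::assay(X)
  else as.matrix(X)
}

#' Mean absolute reconstruction error
#'
#' `sum(|X - Xp|) / (n * T)`: the relative reconstruction error used for
#' NMF rank selection.
#'
#' @param X,Xp matrices of identical shape.
#' @return A nonnegative scalar.
#' @export
relativeError <- function(X, Xp) {
  X <- bpAssay(X); Xp <- bpAssay(Xp)
  if (!identical(dim(X), dim(Xp))) stop("shape mismatch")
  sum(abs(X - Xp)) / (nrow(X) * ncol(X))
}

#' Redundancy between NMF components
#'
#' The strongest correlation or anticorrelation between components:
#' `c = max(max |Corr[W]|, max |Corr[H]|)` over all column pairs of W and
#' row pairs of H (Pearson). Defined as 0 for k = 1.
#'
#' @param W n x k basis matrix.
#' @param H k x T coefficient matrix.
#' @return Scalar in [0, 1].
#' @export
redundancy <- function(W, H) {
  if (ncol(W) != nrow(H)) stop("W and H disagree on k")
  if (ncol(W) < 2) {
    message("redundancy undefined for k = 1; returning 0")
    return(0)
  }
  max(maxAbsCor(W), maxAbsCor(t(H)))
}

# Deterministic sign convention for singular vector pairs.
fixSvdSigns <- function(sv) {
  for (j in seq_len(ncol(sv$u))) {
    s <- sign(sv$u[which.max(abs(sv$u[, j])), j])
    if (s < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  sv
}

#' NNSVD-LRC initialization for NMF
#'
#' Nonnegative SVD with low-rank correction: build nonnegative starting
#' factors from a truncated SVD of rank `ceiling(k/2) + 1` by splitting
#' each rank-1 term into its nonnegative sign parts (ranked by energy),
#' then refine the start with a few multiplicative-update passes against
#' the clamped low-rank approximation (the low-rank correction), which is
#' much cheaper than updates against X itself. Deterministic.
#'
#' @param X nonnegative matrix (or \linkS4class{BandPowerMatrix}).
#' @param k target rank, 1 <= k <= min(n, T).
#' @param lrc_iter correction passes (default 20).
#' @return List with nonnegative matrices `W0` (n x k), `H0` (k x T).
#' @export
nnsvdLrcInit <- function(X, k, lrc_iter = 20) {
  X <- bpAssay(X)
  n <- nrow(X); Tn <- ncol(X)
  if (k < 1 || k > min(n, Tn)) stop("k must lie in [1, min(n, T)]")
  if (any(X < 0)) stop("X must be nonnegative")
  p <- min(ceiling(k / 2) + 1, min(n, Tn))
  sv <- svd(X, nu = p, nv = p)
  sv <- fixSvdSigns(sv)
  d <- sv$d[seq_len(p)]
  W0 <- matrix(0, n, k); H0 <- matrix(0, k, Tn)
  # leading term: nonnegative up to sign for nonnegative X
  u1 <- abs(sv$u[, 1]); v1 <- abs(sv$v[, 1])
  W0[, 1] <- sqrt(d[1]) * u1
  H0[1, ] <- sqrt(d[1]) * v1
  if (k > 1) {
    cand <- list()
    for (j in seq(2, p)) {
      up <- pmax(sv$u[, j], 0); un <- pmax(-sv$u[, j], 0)
      vp <- pmax(sv$v[, j], 0); vn <- pmax(-sv$v[, j], 0)
      cand[[length(cand) + 1]] <- list(u = up, v = vp,
        e = d[j] * sqrt(sum(up^2)) * sqrt(sum(vp^2)), d = d[j])
      cand[[length(cand) + 1]] <- list(u = un, v = vn,
        e = d[j] * sqrt(sum(un^2)) * sqrt(sum(vn^2)), d = d[j])
    }
    ord <- order(vapply(cand, `[[`, numeric(1), "e"), decreasing = TRUE)
    for (s in seq_len(k - 1)) {
      cc <- cand[[ord[s]]]
      nu <- sqrt(sum(cc$u^2)); nv <- sqrt(sum(cc$v^2))
      if (nu * nv == 0) { # rank deficiency: tiny uniform fallback column
        W0[, s + 1] <- mean(X) * 1e-3
        H0[s + 1, ] <- 1
        next
      }
      sc <- sqrt(cc$d * nu * nv)
      W0[, s + 1] <- sc * cc$u / nu
      H0[s + 1, ] <- sc * cc$v / nv
    }
  }
  eps <- 1e-12
  W0 <- pmax(W0, eps); H0 <- pmax(H0, eps)
  # low-rank correction: MU passes against the clamped rank-p approximation
  Xp <- pmax(sv$u %*% (d * t(sv$v)), 0)
  for (i in seq_len(lrc_iter)) {
    H0 <- H0 * (crossprod(W0, Xp)) / (crossprod(W0) %*% H0 + eps)
    W0 <- W0 * (Xp %*% t(H0)) / (W0 %*% tcrossprod(H0) + eps)
  }
  list(W0 = W0, H0 = H0)
}

#' Nonnegative matrix factorization with multiplicative updates
#'
#' Factorizes X ~ W x H (Frobenius objective) starting from the
#' NNSVD-LRC initialization, refining with multiplicative updates until
#' the relative objective change drops below `tol` or `max_iter` sweeps.
#' The objective is non-increasing across sweeps; non-convergence is not
#' an error (a warning is issued).
#'
#' @param X nonnegative matrix or \linkS4class{BandPowerMatrix}.
#' @param k rank.
#' @param max_iter maximum update sweeps (default 500).
#' @param tol relative objective-change tolerance (default 1e-5).
#' @param init optional list(W0, H0) overriding the NNSVD-LRC start.
#' @return An \linkS4class{NMFFactorization}.
#' @export
nmfFactorize <- function(X, k, max_iter = 500, tol = 1e-5, init = NULL) {
  X <- bpAssay(X)
  if (is.null(init)) init <- nnsvdLrcInit(X, k)
  W <- init$W0; H <- init$H0
  eps <- 1e-12
  obj <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    o <- sqrt(sum((X - W %*% H)^2))
    obj <- c(obj, o)
    if (is.finite(prev) && abs(prev - o) < tol * max(prev, eps)) {
      converged <- TRUE
      break
    }
    prev <- o
  }
  if (!converged)
    warning(sprintf("NMF (k = %d) reached max_iter = %d without meeting tol",
                    k, max_iter))
  new("NMFFactorization",
      W = W, H = H, k = as.integer(k),
      relError = relativeError(X, W %*% H),
      redundancy = if (k >= 2) redundancy(W, H) else 0,
      converged = converged, flagged = FALSE, objective = obj)
}

#' Select the NMF rank by reconstruction error and redundancy
#'
#' Factorizes X for each rank in `k_min:k_max` and returns, among ranks
#' with relative reconstruction error below `err_threshold`, the one with
#' the smallest redundancy c (ties within 1e-12 broken toward the
#' smallest rank). If no rank meets the threshold, the smallest-error
#' factorization is returned flagged.
#'
#' @param X nonnegative matrix or \linkS4class{BandPowerMatrix}.
#' @param k_min,k_max rank range (defaults 3 and 15).
#' @param err_threshold relative-error cutoff (default 0.05).
#' @param ... passed to [nmfFactorize()].
#' @return An \linkS4class{NMFFactorization}; slot `flagged` marks the
#'   fallback path.
#' @export
selectRank <- function(X, k_min = 3, k_max = 15, err_threshold = 0.05, ...) {
  Xm <- bpAssay(X)
  if (k_max > min(dim(Xm))) stop("k_max exceeds min(n, T)")
  fits <- lapply(seq(k_min, k_max), function(k) nmfFactorize(Xm, k, ...))
  errs <- vapply(fits, function(f) f@relError, numeric(1))
  cs <- vapply(fits, function(f) f@redundancy, numeric(1))
  ok <- which(errs < err_threshold)
  if (length(ok)) {
    best <- ok[which(cs[ok] <= min(cs[ok]) + 1e-12)][1]
    fits[[best]]
  } else {
    best <- which.min(errs)
    f <- fits[[best]]
    f@flagged <- TRUE
    message(sprintf(
      "no rank in [%d, %d] reached rel. error < %g; returning k = %d (error %.4g), flagged",
      k_min, k_max, err_threshold, f@k, f@relError))
    f
  }
}
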