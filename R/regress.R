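#' @include AllClasses.R
NULL

#' Default LASSO penalty grid
#'
#' 101 values, `10^seq(-3, 2, by = 0.05)`.
#'
#' @return Numeric vector of penalties.
#' @export
lassoLambdaGrid <- function() 10^seq(-3, 2, by = 0.05)

standardizeCol <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s < 1e-12) return(NULL)
  (v - mean(v)) / s
}

#' Vectorize and standardize distance matrices for regression
#'
#' Takes the upper-triangle entries of the seizure dissimilarity matrix
#' (response) and of every predictor slice (IMF distances, residue
#' distance, temporal distance), and standardizes each to mean 0, SD 1.
#' Constant predictor columns are dropped with a warning; a constant
#' response marks the dataset degenerate (downstream fits report
#' adjusted R-squared 0). Subjects with fewer than six seizures are
#' refused, matching the inclusion rule of the analysis.
#'
#' @param dissimilarity S x S seizure dissimilarity matrix.
#' @param distances a \linkS4class{SeizureDistanceSet} (or (M+2) x S x S
#'   array with dimnames on slice 1).
#' @param min_seizures inclusion threshold (default 6).
#' @return A \linkS4class{RegressionDataset} with S(S-1)/2 observations.
#' @export
buildRegressionDataset <- function(dissimilarity, distances,
                                   min_seizures = 6) {
  if (is(distances, "SeizureDistanceSet")) {
    D <- distances@D
    labels <- distances@labels
  } else {
    D <- distances
    labels <- dimnames(D)[[1]]
    if (is.null(labels)) labels <- sprintf("P%d", seq_len(dim(D)[1]))
  }
  S <- nrow(dissimilarity)
  if (S < min_seizures)
    stop(sprintf(
      "only %d seizures; at least %d are required for the regression",
      S, min_seizures))
  if (dim(D)[2] != S) stop("distance slices do not match dissimilarity size")
  ut <- upper.tri(dissimilarity)
  pairs <- which(ut, arr.ind = TRUE)
  y_raw <- dissimilarity[ut]
  ys <- standardizeCol(y_raw)
  degenerate <- is.null(ys)
  if (degenerate) {
    warning("constant response (all seizure pairs equally dissimilar)")
    ys <- rep(0, length(y_raw))
  }
  Zs <- list(); kept <- character(0); dropped <- character(0)
  for (i in seq_len(dim(D)[1])) {
    z <- standardizeCol(D[i, , ][ut])
    if (is.null(z)) dropped <- c(dropped, labels[i])
    else {
      Zs[[length(Zs) + 1]] <- z
      kept <- c(kept, labels[i])
    }
  }
  if (length(dropped))
    warning("dropped constant predictor(s): ",
            paste(dropped, collapse = ", "))
  Z <- do.call(cbind, Zs)
  colnames(Z) <- kept
  new("RegressionDataset", y = ys, Z = Z, labels = kept,
      dropped = dropped, pairs = pairs, degenerate = degenerate)
}

#' Nonnegative LASSO with 10-fold cross-validated penalty
#'
#' L1-penalised least squares with coefficients clamped at zero, solved
#' by cyclic coordinate descent (compiled) over the penalty grid with
#' warm starts. The penalty is chosen by K-fold cross validation
#' (observations shuffled with the seed, then split into contiguous
#' folds); among penalties whose mean CV MSE ties within 1e-12, the
#' largest (most parsimonious) wins.
#'
#' @param dataset a \linkS4class{RegressionDataset}.
#' @param lambda penalty grid (default [lassoLambdaGrid()]).
#' @param n_folds folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return List: `lambda` (selected), `beta` (named nonnegative
#'   coefficients), `selected` (labels with beta > 1e-10), `cvm` (mean CV
#'   MSE per penalty), `path` (p x L coefficient matrix).
#' @export
nonnegLassoCV <- function(dataset, lambda = lassoLambdaGrid(),
                          n_folds = 10, seed = 1) {
  stopifnot(length(lambda) > 0)
  y <- dataset@y; Z <- dataset@Z
  n <- length(y)
  if (n < n_folds) stop("fewer observations than folds")
  # observations shuffled, then contiguous fold blocks of the shuffled order
  ord <- withSeed(seed, sample.int(n))
  fold <- integer(n)
  fold[ord] <- as.integer(cut(seq_len(n), breaks = n_folds, labels = FALSE))
  mse <- .cpp_nnlasso_cv(Z, y, lambda, fold, n_folds)
  cvm <- rowMeans(mse)
  best <- max(which(cvm <= min(cvm) + 1e-12))
  path <- .cpp_nnlasso_path(Z, y, lambda)
  beta <- path[, best]
  names(beta) <- colnames(Z)
  rownames(path) <- colnames(Z)
  list(lambda = lambda[best], beta = beta,
       selected = colnames(Z)[beta > 1e-10],
       cvm = cvm, lambda_grid = lambda, path = path)
}

#' OLS refit on the LASSO-selected predictors
#'
#' Unconstrained ordinary least squares with intercept on the selected
#' (standardized) predictors, reporting coefficients with 95%
#' t-distribution confidence intervals and the adjusted R-squared
#' `1 - (1 - R^2)(N - 1)/(N - p - 1)`. An empty selection yields
#' adjusted R-squared 0 and a flag.
#'
#' @param dataset a \linkS4class{RegressionDataset}.
#' @param selected character vector of predictor labels.
#' @return A \linkS4class{RegressionResult} (permutation slots empty).
#' @export
olsRefit <- function(dataset, selected) {
  n <- length(dataset@y)
  empty_res <- function(flag) new(
    "RegressionResult", lambda = NA_real_, beta = numeric(0),
    selected = character(0),
    coefficients = data.frame(predictor = character(0),
                              estimate = numeric(0), ci_lo = numeric(0),
                              ci_hi = numeric(0)),
    adjR2 = 0, pRandomTimes = numeric(0), pShuffledOrder = numeric(0),
    nObs = as.integer(n), flags = flag)
  if (dataset@degenerate) return(empty_res("degenerate"))
  if (!length(selected)) return(empty_res("empty-selection"))
  sel <- match(selected, dataset@labels)
  if (anyNA(sel)) stop("unknown predictor label")
  p <- length(sel)
  if (n <= p + 1) stop("too few observations for the OLS refit")
  Zs <- dataset@Z[, sel, drop = FALSE]
  fit <- lm(dataset@y ~ Zs)
  r2 <- summary(fit)$r.squared
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  est <- coef(fit)[-1]
  se <- summary(fit)$coefficients[-1, 2]
  tq <- qt(0.975, df = n - p - 1)
  new("RegressionResult", lambda = NA_real_, beta = numeric(0),
      selected = selected,
      coefficients = data.frame(predictor = selected,
                                estimate = unname(est),
                                ci_lo = unname(est - tq * se),
                                ci_hi = unname(est + tq * se)),
      adjR2 = adj, pRandomTimes = numeric(0), pShuffledOrder = numeric(0),
      nObs = as.integer(n), flags = character(0))
}

# One complete fit: LASSO penalty selection + OLS refit; returns the
# RegressionResult with the LASSO slots filled in.
fitDataset <- function(dataset, lambda = lassoLambdaGrid(),
                       n_folds = 10, seed = 1) {
  if (dataset@degenerate) {
    res <- olsRefit(dataset, character(0))
    res@flags <- "degenerate"
    return(res)
  }
  las <- nonnegLassoCV(dataset, lambda, n_folds, seed)
  res <- olsRefit(dataset, las$selected)
  res@lambda <- las$lambda
  res@beta <- las$beta
  res
}

# Rebuild the predictor stack for arbitrary (0-based) onset epochs.
distancesForEpochs <- function(recon, epochs0, onsets_s, lag = 0) {
  M <- length(recon$imf)
  S <- length(epochs0)
  D <- array(0, dim = c(M + 2, S, S))
  ep <- epochs0 - lag
  for (i in seq_len(M)) D[i, , ] <- unname(columnDistance(recon$imf[[i]], ep))
  D[M + 1, , ] <- unname(columnDistance(recon$residue, ep))
  D[M + 2, , ] <- abs(outer(onsets_s, onsets_s, "-"))
  dimnames(D) <- list(c(sprintf("IMF%d", seq_len(M)), "residue", "temporal"),
                      NULL, NULL)
  D
}

#' Permutation test: random seizure onset times
#'
#' Significance of the observed adjusted R-squared against a null where
#' the S onset epochs are redrawn uniformly (i.i.d., unsorted) over the
#' recording; each iteration rebuilds every distance predictor at the
#' random epochs, reruns the penalty selection and OLS refit with the
#' response unchanged, and records the adjusted R-squared. The p-value
#' is the plain fraction of permuted values strictly larger than the
#' observed one (`corrected = TRUE` uses (b+1)/(n+1) instead).
#'
#' @param dissimilarity S x S seizure dissimilarity matrix.
#' @param recon [reconstructImfSpace()] output (W and IMFs in band/
#'   channel space).
#' @param seizures a \linkS4class{SeizureTable}.
#' @param n_iter permutation iterations (default 500).
#' @param seed integer seed.
#' @param lag epochs to step back from onsets.
#' @param lambda,n_folds passed to [nonnegLassoCV()].
#' @param observed optional precomputed observed adjusted R-squared.
#' @param corrected use the (b+1)/(n+1) p-value (default FALSE).
#' @return List: `p`, `observed`, `permuted` (vector of null adjusted
#'   R-squared values).
#' @export
permutationTestRandomTimes <- function(dissimilarity, recon, seizures,
                                       n_iter = 500, seed = 1, lag = 0,
                                       lambda = lassoLambdaGrid(),
                                       n_folds = 10, observed = NULL,
                                       corrected = FALSE) {
  Tn <- ncol(recon$residue)
  S <- length(seizures@onsets_s)
  epoch_s <- seizures@epoch_s
  if (is.null(observed)) {
    ds <- buildRegressionDataset(
      dissimilarity, seizureDistances(NULL, NULL, seizures, lag,
                                      recon = recon))
    observed <- fitDataset(ds, lambda, n_folds,
                           seed = deriveSeed(seed, 0))@adjR2
  }
  permuted <- withSeed(deriveSeed(seed, 1), {
    vapply(seq_len(n_iter), function(it) {
      ep <- sample.int(Tn, S, replace = TRUE) - 1L
      ep <- pmax(ep, lag)
      D <- distancesForEpochs(recon, ep, ep * epoch_s, lag)
      ds <- suppressWarnings(buildRegressionDataset(dissimilarity, D))
      suppressWarnings(
        fitDataset(ds, lambda, n_folds, seed = deriveSeed(seed, 1 + it))@adjR2)
    }, numeric(1))
  })
  b <- sum(permuted > observed)
  p <- if (corrected) (b + 1) / (n_iter + 1) else b / n_iter
  list(p = p, observed = observed, permuted = permuted)
}

#' Permutation test: shuffled seizure order
#'
#' Null where which-seizure-maps-to-which-onset is permuted without
#' touching the onset times: the rows/columns of the dissimilarity
#' matrix are relabelled relative to the (unchanged) distance
#' predictors, and the model is refit. Identity permutations are
#' allowed. A degenerate (constant) response reports p = 1.
#'
#' @inheritParams permutationTestRandomTimes
#' @param distances a \linkS4class{SeizureDistanceSet} for the observed
#'   onsets.
#' @return List: `p`, `observed`, `permuted`.
#' @export
permutationTestShuffledOrder <- function(dissimilarity, distances,
                                         n_iter = 500, seed = 1,
                                         lambda = lassoLambdaGrid(),
                                         n_folds = 10, observed = NULL,
                                         corrected = FALSE) {
  S <- nrow(dissimilarity)
  ds0 <- suppressWarnings(buildRegressionDataset(dissimilarity, distances))
  if (ds0@degenerate)
    return(list(p = 1, observed = 0, permuted = rep(0, n_iter)))
  if (is.null(observed))
    observed <- fitDataset(ds0, lambda, n_folds,
                           seed = deriveSeed(seed, 0))@adjR2
  permuted <- withSeed(deriveSeed(seed, 2), {
    vapply(seq_len(n_iter), function(it) {
      pr <- sample.int(S)
      dp <- dissimilarity[pr, pr]
      ds <- suppressWarnings(buildRegressionDataset(dp, distances))
      suppressWarnings(
        fitDataset(ds, lambda, n_folds, seed = deriveSeed(seed, 2 + it))@adjR2)
    }, numeric(1))
  })
  b <- sum(permuted > observed)
  p <- if (corrected) (b + 1) / (n_iter + 1) else b / n_iter
  list(p = p, observed = observed, permuted = permuted)
}

#' Explain seizure dissimilarity from IMF seizure distances
#'
#' The full association stage: builds the standardized seizure-pair
#' dataset (response: DTW seizure dissimilarity; predictors: per-IMF,
#' residue and temporal distances), selects predictors with the
#' nonnegativity-constrained LASSO (10-fold CV penalty), refits OLS for
#' coefficients/CIs and adjusted R-squared, and (optionally) runs both
#' permutation significance tests.
#'
#' @param dissimilarity S x S seizure dissimilarity matrix.
#' @param W NMF basis or \linkS4class{NMFFactorization}.
#' @param imfset an \linkS4class{IMFSet}.
#' @param seizures a \linkS4class{SeizureTable}.
#' @param lag epochs to step back from onsets (default 0).
#' @param lambda penalty grid.
#' @param n_folds CV folds.
#' @param n_perm permutation iterations (0 skips the tests).
#' @param seed master seed.
#' @return A \linkS4class{RegressionResult}.
#' @export
regressDissimilarity <- function(dissimilarity, W, imfset, seizures,
                                 lag = 0, lambda = lassoLambdaGrid(),
                                 n_folds = 10, n_perm = 500, seed = 1) {
  recon <- reconstructImfSpace(W, imfset)
  dists <- seizureDistances(W, imfset, seizures, lag, recon = recon)
  ds <- buildRegressionDataset(dissimilarity, dists)
  res <- fitDataset(ds, lambda, n_folds, seed = deriveSeed(seed, 0))
  if (n_perm > 0) {
    rt <- permutationTestRandomTimes(dissimilarity, recon, seizures,
                                     n_iter = n_perm, seed = seed, lag = lag,
                                     lambda = lambda, n_folds = n_folds,
                                     observed = res@adjR2)
    so <- permutationTestShuffledOrder(dissimilarity, dists,
                                       n_iter = n_perm, seed = seed,
                                       lambda = lambda, n_folds = n_folds,
                                       observed = res@adjR2)
    res@pRandomTimes <- rt$p
    res@pShuffledOrder <- so$p
  }
  res
}
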