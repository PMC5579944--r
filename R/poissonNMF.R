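## Poisson-likelihood NMF with Kullback-Leibler multiplicative updates.
## Maximizing L(T,W) = sum_ij X_ij log(TW)_ij - (TW)_ij over non-negative
## T, W is equivalent (up to constants in X) to minimizing the generalized
## KL divergence D(X || TW); the Lee-Seung multiplicative updates for that
## divergence are therefore monotone in L. Type columns are renormalized
## to unit sum after every sweep, with the scale absorbed into W, which
## leaves the product TW unchanged.

.TW_FLOOR <- 1e-12

#' Poisson log-likelihood of a factorization
#'
#' Computes \eqn{L(T,W) = \sum_{ij} X_{ij} \log(TW)_{ij} - (TW)_{ij}}
#' (the saturated-model constant \eqn{\log X_{ij}!} is dropped). A cell
#' with \eqn{X_{ij} = 0} contributes \eqn{-(TW)_{ij}} even when
#' \eqn{(TW)_{ij} = 0}; a zero mean against a positive count yields
#' `-Inf`.
#'
#' @param X count matrix (p x n).
#' @param types type matrix T (p x k), non-negative.
#' @param weights weight matrix W (k x n) on the raw depth scale.
#' @return scalar log-likelihood.
#' @export
#' @examples
#' poissonLogLik(matrix(2), matrix(1), matrix(2))  # 2*log(2) - 2
poissonLogLik <- function(X, types, weights) {
  X <- as.matrix(X); types <- as.matrix(types); weights <- as.matrix(weights)
  if (nrow(types) != nrow(X) || ncol(weights) != ncol(X) ||
      ncol(types) != nrow(weights))
    stop("dimension mismatch between X, types and weights")
  if (any(X < 0) || any(types < 0) || any(weights < 0))
    stop("negative entries are not allowed")
  M <- types %*% weights
  pos <- X > 0
  if (any(M[pos] == 0)) return(-Inf)
  sum(X[pos] * log(M[pos])) - sum(M)
}

## One multiplicative update sweep (T then W), with T-column
## renormalization absorbed into W. Zero-count-supported cells are
## floored at .TW_FLOOR inside ratios to avoid 0/0.
.nmfSweep <- function(X, Tm, Wm) {
  M <- Tm %*% Wm
  R <- X / pmax(M, .TW_FLOOR)
  Tm <- Tm * (R %*% t(Wm)) / pmax(matrix(rowSums(Wm), nrow(Tm), ncol(Tm),
                                         byrow = TRUE), .TW_FLOOR)
  cs <- colSums(Tm)
  cs[cs == 0] <- 1
  Tm <- sweep(Tm, 2, cs, "/")
  Wm <- Wm * cs
  M <- Tm %*% Wm
  R <- X / pmax(M, .TW_FLOOR)
  ## with unit-sum T columns the W-update denominator colSums(T) is 1
  Wm <- Wm * (t(Tm) %*% R)
  list(types = Tm, weights = Wm)
}

#' Fit Poisson NMF
#'
#' Factorizes a count matrix as \eqn{X \approx TW} by maximizing the
#' Poisson log-likelihood with multiplicative (KL) updates. Type columns
#' are constrained to sum to 1, so sequencing depth is absorbed by W: the
#' column sums of the fitted raw W equal the column sums of X.
#'
#' Entries of T and W are initialized uniform on (0, 1] and scaled so the
#' initial TW matches the total count of X. Convergence is declared when
#' the relative log-likelihood improvement over a sweep falls below `tol`.
#'
#' @param X count matrix (features x samples); see [asCountMatrix()].
#' @param k number of types, `1 <= k <= min(p, n)`.
#' @param seed integer seed for the random initialization (required; the
#'   NMF solution is not always unique, so the seed is part of the
#'   result's provenance).
#' @param maxIter maximum number of update sweeps.
#' @param tol relative log-likelihood improvement threshold.
#' @return a [PoissonNMF-class] object.
#' @export
#' @examples
#' X <- matrix(rpois(200, 10), nrow = 20)
#' fit <- fitNMF(X, k = 2, seed = 1)
#' colSums(weightMatrix(fit))  # equals colSums(X)
fitNMF <- function(X, k, seed, maxIter = 2000L, tol = 1e-6) {
  X <- asCountMatrix(X, requireIntegers = FALSE)
  p <- nrow(X); n <- ncol(X)
  if (length(k) != 1 || k < 1 || k > min(p, n))
    stop("k must satisfy 1 <= k <= min(p, n)")
  k <- as.integer(k)
  seed <- as.integer(seed)
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(seed)
  Tm <- matrix(1 - runif(p * k), p, k)  # uniform on (0, 1]
  Wm <- matrix(1 - runif(k * n), k, n)
  Tm <- normalizeColumns(Tm)
  ## scale W so each initial column of TW has the depth of X's column
  Wm <- sweep(Wm, 2, colSums(X) / colSums(Wm), "*")

  trace <- numeric(maxIter)
  ll <- poissonLogLik(X, Tm, Wm)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxIter)) {
    st <- .nmfSweep(X, Tm, Wm)
    Tm <- st$types; Wm <- st$weights
    llNew <- .loglikFloored(X, Tm, Wm)
    trace[it] <- llNew
    iter <- it
    if (is.finite(ll) && abs(llNew - ll) <= tol * abs(ll)) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  dimnames(Tm) <- list(rownames(X), paste0("type", seq_len(k)))
  dimnames(Wm) <- list(colnames(Tm), colnames(X))
  new("PoissonNMF", types = Tm, weights = Wm, loglik = ll,
      loglikTrace = trace[seq_len(iter)], nIter = iter,
      converged = converged, seed = seed)
}

## likelihood with the machine floor used inside the optimizer, so the
## trace is finite (and monotone) even while some means are still ~0
.loglikFloored <- function(X, Tm, Wm) {
  M <- pmax(Tm %*% Wm, .TW_FLOOR)
  pos <- X > 0
  sum(X[pos] * log(M[pos])) - sum(M)
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

## deterministic stream of sub-seeds below 2^31
.subSeeds <- function(seed, n) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

#' Best log-likelihood over a grid of type numbers
#'
#' Fits `nStarts` random restarts of [fitNMF()] for each k and keeps the
#' best likelihood, for locating the elbow of the likelihood curve. The
#' curve must be non-decreasing in k (models are nested); if restarts were
#' insufficient to realize that empirically, a warning is raised.
#'
#' @param X count matrix.
#' @param kGrid increasing integer vector of candidate k.
#' @param seed integer seed.
#' @param nStarts restarts per k.
#' @param ... passed to [fitNMF()].
#' @return named numeric vector, best log-likelihood per k.
#' @export
logLikCurve <- function(X, kGrid, seed, nStarts = 10L, ...) {
  kGrid <- as.integer(kGrid)
  if (is.unsorted(kGrid, strictly = TRUE))
    stop("kGrid must be sorted ascending")
  seeds <- matrix(.subSeeds(seed, length(kGrid) * nStarts),
                  nrow = length(kGrid))
  best <- vapply(seq_along(kGrid), function(i) {
    max(vapply(seq_len(nStarts), function(s)
      fitNMF(X, kGrid[i], seed = seeds[i, s], ...)@loglik, numeric(1)))
  }, numeric(1))
  names(best) <- kGrid
  if (is.unsorted(best))
    warning("log-likelihood curve not non-decreasing; increase nStarts")
  best
}

#' Elbow of a log-likelihood curve
#'
#' Locates the k with the largest negative second difference (maximum
#' curvature) of the likelihood curve, the usual elbow heuristic for
#' choosing the number of types in unsupervised fits.
#'
#' @param curve named vector from [logLikCurve()].
#' @return the k at the elbow.
#' @export
elbowPoint <- function(curve) {
  if (length(curve) < 3) stop("need at least 3 grid points")
  d2 <- diff(curve, differences = 2)
  as.integer(names(curve)[which.min(d2) + 1L])
}
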