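## Non-negative identity-link Poisson regression of one sample on a type
## matrix: maximize L(w) = sum_i x_i log((Tw)_i) - (Tw)_i over w >= 0,
## with no intercept. The discrete part (which coefficients are zero) is
## handled by a backwards-forwards search: fit unconstrained, drop
## negative coefficients until all are non-negative, then test each
## dropped variable for re-entry by evaluating the likelihood at a small
## epsilon weight (after rescaling the coefficient vector back to the
## sample depth). Each accepted re-entry strictly increases the
## likelihood, which guarantees termination over the finite set of active
## subsets.

## Unconstrained (in sign of w) identity-link Poisson fit by Newton with
## step-halving; fitted means are kept strictly positive throughout, which
## keeps the likelihood concave and bounded. Rows whose T entries are all
## zero are constant in w and excluded.
.poissonIdentityFit <- function(Tact, x, winit = NULL, maxit = 200L,
                                tol = 1e-12) {
  keep <- rowSums(Tact) > 0
  Tr <- Tact[keep, , drop = FALSE]
  xr <- x[keep]
  k <- ncol(Tr)
  depth <- sum(xr)
  if (depth == 0) {
    ## every count sits outside the support of the active types: the
    ## -mu penalty drives all coefficients to the boundary at zero
    return(list(weights = rep(0, k), loglik = 0))
  }
  xpos <- xr > 0

  ## means must stay positive where a count was observed and
  ## non-negative elsewhere
  ll <- function(w) {
    mu <- drop(Tr %*% w)
    if (any(mu < 0) || any(mu[xpos] == 0)) return(-Inf)
    sum(xr[xpos] * log(mu[xpos])) - sum(mu)
  }
  ## least-squares start (Appendix-style), pulled toward the feasible
  ## equal-split point until all fitted means are positive
  w <- tryCatch(qr.solve(Tr, xr), error = function(e) NULL)
  wfeas <- rep(depth / k, k)
  if (is.null(w)) w <- wfeas
  a <- 1
  while (!is.finite(ll(w)) && a > 1e-12) {
    a <- a / 2
    w <- a * w + (1 - a) * wfeas
  }
  if (!is.finite(ll(w))) w <- wfeas
  f <- ll(w)

  for (it in seq_len(maxit)) {
    mu <- drop(Tr %*% w)
    g <- drop(t(Tr[xpos, , drop = FALSE]) %*% (xr[xpos] / mu[xpos])) -
      colSums(Tr)
    Hd <- xr[xpos] / mu[xpos]^2
    H <- crossprod(Tr[xpos, , drop = FALSE] * sqrt(Hd))
    step <- tryCatch(solve(H + diag(1e-10, k), g),
                     error = function(e) g)
    s <- 1
    fNew <- ll(w + s * step)
    while ((!is.finite(fNew) || fNew < f) && s > 1e-14) {
      s <- s / 2
      fNew <- ll(w + s * step)
    }
    if (!is.finite(fNew) || fNew < f) break
    moved <- fNew - f
    w <- w + s * step
    f <- fNew
    if (moved <= tol * (abs(f) + 1)) break
    if (it == maxit)
      stop("identity-link Poisson fit did not converge: ",
           sprintf("k=%d, depth=%g, grad max=%.3g", k, depth, max(abs(g))))
  }
  list(weights = w, loglik = f)
}

#' Non-negative Poisson regression of one sample on a type matrix
#'
#' Fits per-sample non-negative coefficients of an intercept-free,
#' identity-link Poisson regression by the backwards-forwards algorithm:
#' (1) unconstrained fit initialized from least squares, (2) batch removal
#' of variables with negative coefficients until all are non-negative,
#' (3) record the likelihood of the active set, (4) test each removed
#' variable by evaluating the likelihood at weight `epsilon` (coefficients
#' rescaled so their sum equals the sample depth), (5) re-admit and refit
#' when the likelihood increases. When every type column sums to 1, the
#' returned coefficients sum to the sample depth.
#'
#' @param types type matrix (p x k), unit column sums.
#' @param x length-p count vector with at least one positive entry.
#' @param epsilon re-entry test weight (default 1e-7).
#' @return list with `weights` (length-k, non-negative, named by type),
#'   `activeSet` (indices with positive weight), `loglik`, `nOuterIter`,
#'   and `loglikTrace` (likelihood after each accept/refit cycle).
#' @export
#' @examples
#' Tm <- cbind(c(0.8, 0.2), c(0.2, 0.8))
#' fitWeights(Tm, c(10, 0))$weights  # boundary optimum (10, 0)
fitWeights <- function(types, x, epsilon = 1e-7) {
  types <- as.matrix(types)
  x <- as.numeric(x)
  if (length(x) != nrow(types)) stop("length(x) must equal nrow(types)")
  if (any(x < 0)) stop("negative counts")
  if (sum(x) == 0) stop("x is all zeros: weights are undefined")
  k <- ncol(types)
  depth <- sum(x)

  refit <- function(active) {
    ## steps 1-2: fit, drop negatives, repeat
    repeat {
      fit <- .poissonIdentityFit(types[, active, drop = FALSE], x)
      neg <- fit$weights < 0
      if (!any(neg)) return(list(active = active, weights = fit$weights,
                                 loglik = fit$loglik))
      if (all(neg)) {
        ## degenerate: keep the single best column
        active <- active[which.max(fit$weights)]
      } else active <- active[!neg]
    }
  }

  state <- refit(seq_len(k))
  trace <- state$loglik
  nOuter <- 1L
  repeat {
    removed <- setdiff(seq_len(k), state$active)
    admitted <- FALSE
    for (v in removed) {   # original column order (deterministic)
      wNew <- c(state$weights * (1 - epsilon), epsilon)
      wNew <- wNew * depth / sum(wNew)
      Tnew <- types[, c(state$active, v), drop = FALSE]
      llNew <- {
        mu <- drop(Tnew %*% wNew)
        pos <- x > 0
        if (any(mu[pos] <= 0)) -Inf else sum(x[pos] * log(mu[pos])) - sum(mu)
      }
      if (llNew > state$loglik) {
        cand <- refit(c(state$active, v))
        nOuter <- nOuter + 1L
        if (cand$loglik <= state$loglik) break  # numeric guard: no ascent
        state <- cand
        trace <- c(trace, state$loglik)
        admitted <- TRUE
        break
      }
    }
    if (!admitted) break
  }

  w <- numeric(k)
  w[state$active] <- state$weights
  names(w) <- colnames(types)
  list(weights = w, activeSet = sort(state$active[state$weights > 0]),
       loglik = state$loglik, nOuterIter = nOuter, loglikTrace = trace)
}

#' Poisson deviance
#'
#' \eqn{2 \sum_i x_i \log(x_i/\mu_i) - (x_i - \mu_i)} with the convention
#' \eqn{0 \log 0 = 0}. A zero mean against a positive count gives `Inf`
#' (returned, not thrown).
#'
#' @param x count vector.
#' @param mu fitted mean vector (non-negative).
#' @return scalar deviance.
#' @export
poissonDeviance <- function(x, mu) {
  if (length(x) != length(mu)) stop("length mismatch")
  if (any(mu < 0)) stop("negative means")
  if (any(mu == 0 & x > 0)) return(Inf)
  pos <- x > 0
  2 * (sum(x[pos] * log(x[pos] / mu[pos])) - sum(x - mu))
}

#' Project samples onto a fixed type matrix
#'
#' Applies [fitWeights()] to every column of a count matrix independently
#' (for fixed T the per-sample regressions are independent) and reports
#' the raw weight matrix together with each sample's Poisson deviance
#' against its fitted mean \eqn{T w_j}.
#'
#' @param types type matrix with feature rownames.
#' @param X count matrix; features are aligned with `types` by ID
#'   (mismatches are an error listing the offending IDs).
#' @param epsilon re-entry test weight, see [fitWeights()].
#' @return list with `weights` (k x n raw weight matrix) and `deviances`
#'   (length-n vector).
#' @export
transformSamples <- function(types, X, epsilon = 1e-7) {
  X <- asCountMatrix(X, requireIntegers = FALSE)
  X <- alignFeatures(types, X)
  n <- ncol(X)
  W <- matrix(0, ncol(types), n,
              dimnames = list(colnames(types), colnames(X)))
  dev <- numeric(n)
  for (j in seq_len(n)) {
    fit <- fitWeights(types, X[, j], epsilon = epsilon)
    W[, j] <- fit$weights
    dev[j] <- poissonDeviance(X[, j], drop(types %*% fit$weights))
  }
  names(dev) <- colnames(X)
  list(weights = W, deviances = dev)
}
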