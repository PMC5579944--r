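## Choosing the number of types per class: cross-validated deviances,
## fold-wise Wilcoxon rank-sum Z statistics, the combined statistic
## Z_all = sum(Z_f)/sqrt(r), and the smallest-k-within-one-SD rule. The
## SD is the sample SD of the fold Z values, not the null value 1: the
## goal is the k that best *separates* the deviance distributions, not a
## hypothesis test.

#' Standardized Wilcoxon rank-sum statistic on deviances
#'
#' Pools the two deviance samples, ranks them (midranks for ties), and
#' standardizes the rank sum of `devOther` by its null mean
#' \eqn{m(n+m+1)/2} and tie-corrected variance. The sign convention is
#' Z > 0 when the other class's deviances tend to be larger, i.e. the
#' fitted types describe their own class better. If all pooled values are
#' tied the statistic is 0.
#'
#' @param devOwn deviances of the own-class test fold.
#' @param devOther deviances of the other class's fold.
#' @return scalar Z value.
#' @export
#' @examples
#' wilcoxonZ(c(1, 2, 3), c(4, 5, 6))  # ~1.964
wilcoxonZ <- function(devOwn, devOther) {
  nO <- length(devOwn); m <- length(devOther)
  if (nO == 0 || m == 0) stop("both deviance vectors must be non-empty")
  pooled <- c(devOwn, devOther)
  ## infinite deviances rank above everything finite; rank() handles Inf
  r <- rank(pooled)
  W <- sum(r[(nO + 1):(nO + m)])
  N <- nO + m
  mu <- m * (N + 1) / 2
  ties <- table(pooled)
  tieCorr <- sum(ties^3 - ties)
  v <- nO * m / 12 * ((N + 1) - tieCorr / (N * (N - 1)))
  if (v <= 0) return(0)
  (W - mu) / sqrt(v)
}

#' Choose the number of types for one class
#'
#' For each candidate k: fit k types on the own-class training folds,
#' compute deviances of the own-class test fold and of the paired fold of
#' the other class(es) against those types (via non-negative Poisson
#' regression), and form one Wilcoxon Z per fold. The combined statistic
#' is \eqn{Z_{all} = \sum_f Z_f/\sqrt{r}}; its standard deviation is the
#' sample SD of the fold Z values. The chosen k is the smallest candidate
#' whose \eqn{Z_{all}} is within one such SD of the largest
#' \eqn{Z_{all}}.
#'
#' The other class is split into the same number of folds (same seed) and
#' paired fold-for-fold with the own-class folds; with more than one
#' other class the paired folds are pooled.
#'
#' @param Xown count matrix of the class whose type number is selected.
#' @param Xothers count matrix of the remaining class(es), or a list of
#'   such matrices.
#' @param kGrid candidate numbers of types (default 1:10).
#' @param r number of cross-validation folds.
#' @param seed integer seed.
#' @param epsilon re-entry weight of the Poisson regression.
#' @param ... passed to [fitNMF()].
#' @return a [TypeSelection-class] report. A (k, fold) pair whose fit is
#'   infeasible is recorded as NA; a k with more than 20% missing folds
#'   is excluded from the selection rule.
#' @export
selectNumTypes <- function(Xown, Xothers, kGrid = 1:10, r = 10L, seed = 1L,
                           epsilon = 1e-7, ...) {
  Xown <- asCountMatrix(Xown, requireIntegers = FALSE)
  if (!is.list(Xothers)) Xothers <- list(Xothers)
  Xothers <- lapply(Xothers, asCountMatrix, requireIntegers = FALSE)
  kGrid <- sort(as.integer(kGrid))
  r <- as.integer(r)
  nOwn <- ncol(Xown)
  if (nOwn < r) stop("own class needs at least r samples")

  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  foldsOwn <- sample(rep(seq_len(r), length.out = nOwn))
  foldsOth <- lapply(Xothers, function(Xo)
    sample(rep(seq_len(r), length.out = ncol(Xo))))
  fitSeeds <- matrix(sample.int(2147483646L, length(kGrid) * r),
                     nrow = length(kGrid))

  Z <- matrix(NA_real_, r, length(kGrid),
              dimnames = list(NULL, paste0("k", kGrid)))
  for (ik in seq_along(kGrid)) {
    k <- kGrid[ik]
    for (f in seq_len(r)) {
      trainIdx <- which(foldsOwn != f)
      if (k > length(trainIdx)) next  # infeasible -> NA
      fit <- tryCatch(
        fitNMF(Xown[, trainIdx, drop = FALSE], k,
               seed = fitSeeds[ik, f], ...),
        error = function(e) NULL)
      if (is.null(fit)) next
      Tm <- typeMatrix(fit)
      devOwn <- transformSamples(
        Tm, Xown[, foldsOwn == f, drop = FALSE],
        epsilon = epsilon)$deviances
      devOther <- unlist(lapply(seq_along(Xothers), function(i)
        transformSamples(Tm, Xothers[[i]][, foldsOth[[i]] == f,
                                          drop = FALSE],
                         epsilon = epsilon)$deviances))
      Z[f, ik] <- wilcoxonZ(devOwn, devOther)
    }
  }

  zAll <- colSums(Z, na.rm = TRUE) / sqrt(r)
  sdZ <- apply(Z, 2, sd, na.rm = TRUE)
  usable <- colMeans(is.na(Z)) <= 0.2
  if (!any(usable)) stop("no candidate k with enough successful folds")
  chosen <- .smallestKRule(kGrid, zAll, sdZ, usable)

  new("TypeSelection", kGrid = kGrid, zByFold = Z,
      zAll = unname(zAll), sdZAll = unname(sdZ),
      chosenK = as.integer(chosen), folds = r)
}

## the smallest candidate whose Z_all is within one (empirical) SD of the
## largest Z_all among usable candidates
.smallestKRule <- function(kGrid, zAll, sdZ, usable = rep(TRUE, length(kGrid))) {
  iMax <- which(zAll == max(zAll[usable]) & usable)[1]
  threshold <- zAll[iMax] - sdZ[iMax]
  kGrid[usable & zAll >= threshold][1]
}

#' Refine the type number of a hard class by cross-validated error
#'
#' When the Wilcoxon procedure is clear-cut for some classes but not for
#' another, the clear ("easy") classes are fixed and the remaining class's
#' type number is chosen to minimize the mean cross-validated
#' classification error, ties broken toward the smaller k.
#'
#' @param X count matrix with samples from all classes.
#' @param labels class labels.
#' @param fixedK named vector of type numbers for the fixed classes.
#' @param hardClass name of the class whose k is selected.
#' @param kGridHard candidate k values for the hard class.
#' @param r folds for [crossValidate()].
#' @param seed integer seed.
#' @param ... passed to [crossValidate()].
#' @return list with `chosenK`, `cvMeans` (named mean CV error per
#'   candidate) and the per-candidate [crossValidate()] results.
#' @export
refineByCVError <- function(X, labels, fixedK, hardClass, kGridHard,
                            r = 10L, seed = 1L, ...) {
  labels <- checkPartition(labels, ncol(as.matrix(X)))
  if (!hardClass %in% levels(labels)) stop("unknown hard class")
  if (!all(setdiff(levels(labels), hardClass) %in% names(fixedK)))
    stop("fixedK must cover every class except the hard one")
  kGridHard <- sort(as.integer(kGridHard))
  cvs <- lapply(kGridHard, function(k) {
    kBy <- c(fixedK, stats::setNames(k, hardClass))
    crossValidate(X, labels, kByClass = kBy, nFolds = r, seed = seed, ...)
  })
  means <- vapply(cvs, `[[`, numeric(1), "mean")
  names(means) <- kGridHard
  list(chosenK = kGridHard[which.min(means)], cvMeans = means,
       cvResults = cvs)
}
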