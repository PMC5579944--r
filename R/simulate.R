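## Generators used to benchmark the method: the NMF-generative sampler
## with SNR-controlled Gaussian perturbation of the Poisson mean,
## zero-inflated Dirichlet weights, outlier mislabeling, and the
## McMurdie-Holmes style effect-size mixture classes.

#' Per-row noise standard deviations for a given SNR
#'
#' The generative simulation perturbs the Poisson mean \eqn{TW} with
#' Gaussian noise whose per-row standard deviation is \eqn{sd(T)/SNR},
#' where \eqn{sd(T)} is the row-wise standard deviation of the type
#' matrix (the variability of each feature across types). `snr = Inf`
#' gives exactly zero noise.
#'
#' @param types type matrix.
#' @param snr one of `Inf`, 4, 2, 1.
#' @return length-p vector of standard deviations.
#' @export
noiseSd <- function(types, snr = Inf) {
  if (!snr %in% c(Inf, 4, 2, 1))
    stop("snr must be one of Inf, 4, 2, 1")
  if (is.infinite(snr)) return(numeric(nrow(types)))
  apply(types, 1, sd) / snr
}

#' Simulate counts from a type matrix
#'
#' Draws weight columns uniform on (0,1) normalized to the requested
#' column sums (sequencing depths), forms the mean \eqn{M = TW + \epsilon}
#' with \eqn{\epsilon_{ij} \sim N(0, sd_i)} (negative means clamped to 0),
#' and samples \eqn{X_{ij} \sim Poisson(M_{ij})} independently.
#'
#' @param types type matrix (unit column sums).
#' @param colSums per-sample depths (length n, positive).
#' @param sdVector per-row noise SDs, e.g. from [noiseSd()]; default no
#'   noise.
#' @param seed integer seed.
#' @return list with `counts` (p x n), `trueWeights` (k x n) and `mean`.
#' @export
simulateFromTypes <- function(types, colSums, sdVector = NULL, seed = 1L) {
  types <- as.matrix(types)
  if (any(colSums <= 0)) stop("column sums must be positive")
  p <- nrow(types); k <- ncol(types); n <- length(colSums)
  if (is.null(sdVector)) sdVector <- numeric(p)
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  W <- matrix(runif(k * n), k, n)
  W <- sweep(W, 2, colSums / .colSums2(W), "*")
  .poissonFromMean(types, W, sdVector)
}

.colSums2 <- function(M) {
  cs <- colSums(M); cs[cs == 0] <- 1; cs
}

.poissonFromMean <- function(types, W, sdVector) {
  p <- nrow(types); n <- ncol(W)
  M <- types %*% W
  if (any(sdVector > 0))
    M <- M + matrix(rnorm(p * n, 0, sdVector), p, n)  # sd recycled by row
  M <- pmax(M, 0)
  X <- matrix(rpois(p * n, M), p, n)
  rownames(X) <- rownames(types) %||% paste0("feature", seq_len(p))
  colnames(X) <- paste0("sample", seq_len(n))
  dimnames(M) <- dimnames(X)
  list(counts = X, trueWeights = W, mean = M)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate counts with zero-inflated weights
#'
#' Like [simulateFromTypes()] but with weight columns drawn from a
#' symmetric Dirichlet with a very small concentration (default 0.005),
#' scaled to the requested depths. The tiny concentration puts almost all
#' mass of each column on one or two types, producing much sparser count
#' tables than the uniform-weight generator.
#'
#' @inheritParams simulateFromTypes
#' @param alpha Dirichlet concentration (> 0).
#' @return as [simulateFromTypes()].
#' @export
simulateZeroInflated <- function(types, colSums, alpha = 0.005,
                                 sdVector = NULL, seed = 1L) {
  types <- as.matrix(types)
  if (alpha <= 0) stop("alpha must be positive")
  if (any(colSums <= 0)) stop("column sums must be positive")
  p <- nrow(types); k <- ncol(types); n <- length(colSums)
  if (is.null(sdVector)) sdVector <- numeric(p)
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  W <- matrix(0, k, n)
  for (j in seq_len(n)) {
    g <- rgamma(k, shape = alpha)
    while (sum(g) == 0) g <- rgamma(k, shape = alpha)  # numeric underflow
    W[, j] <- g / sum(g) * colSums[j]
  }
  .poissonFromMean(types, W, sdVector)
}

#' Flip a fraction of binary labels
#'
#' Flips exactly `round(fraction * n)` labels, chosen uniformly at random
#' without replacement, emulating mislabeled training observations.
#' Applying the same seed twice restores the original labels.
#'
#' @param labels binary label vector (factor or character, two levels).
#' @param fraction fraction to flip, in `[0, 1)`.
#' @param seed integer seed.
#' @return labels with the chosen subset flipped.
#' @export
mislabel <- function(labels, fraction, seed = 1L) {
  lab <- as.factor(labels)
  if (nlevels(lab) != 2)
    stop("mislabel is defined for two-class labels")
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  nFlip <- round(fraction * length(lab))
  if (nFlip == 0) return(lab)
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  idx <- sample(length(lab), nFlip)
  lv <- levels(lab)
  lab[idx] <- lv[3L - as.integer(lab[idx])]
  lab
}

#' Simulate two classes as effect-size mixtures of two base compositions
#'
#' Following the "simulation A" design of clustering benchmarks: two base
#' multinomial probability vectors are mixed in ratios 1 : s and s : 1
#' (s = effect size >= 1) to form the class probabilities
#' \eqn{p_A = (p_1 + s p_2)/(1+s)} and \eqn{p_B = (s p_1 + p_2)/(1+s)},
#' and each sample is a multinomial draw of size `depth`. `s = 1` makes
#' the classes identical.
#'
#' @param pBase1,pBase2 length-p probability vectors (normalized
#'   internally).
#' @param effectSize s >= 1.
#' @param depth sequencing depth per sample.
#' @param nPerClass samples per class.
#' @param seed integer seed.
#' @return list with `counts` (p x 2n) and `labels` (factor "A"/"B").
#' @export
simulateMixtureClasses <- function(pBase1, pBase2, effectSize, depth,
                                   nPerClass, seed = 1L) {
  if (effectSize < 1) stop("effectSize must be >= 1")
  if (length(pBase1) != length(pBase2)) stop("base vectors differ in length")
  p1 <- pBase1 / sum(pBase1); p2 <- pBase2 / sum(pBase2)
  s <- effectSize
  pA <- (p1 + s * p2) / (1 + s)
  pB <- (s * p1 + p2) / (1 + s)
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  XA <- rmultinom(nPerClass, depth, pA)
  XB <- rmultinom(nPerClass, depth, pB)
  X <- cbind(XA, XB)
  rownames(X) <- names(pBase1) %||% paste0("feature", seq_along(p1))
  colnames(X) <- paste0("sample", seq_len(2 * nPerClass))
  list(counts = X,
       labels = factor(rep(c("A", "B"), each = nPerClass)))
}

#' Random sparse type matrix
#'
#' Generates a synthetic sparse type matrix of the kind fitted from real
#' metagenomes: each type has a small random support (default 10% of
#' features, at least 3) with uniform composition values, normalized to
#' sum 1. Used as ground truth for the generative simulations.
#'
#' @param p number of features.
#' @param k number of types.
#' @param supportFraction fraction of features in each type's support.
#' @param seed integer seed.
#' @return p x k type matrix with unit column sums.
#' @export
randomSparseTypes <- function(p, k, supportFraction = 0.1, seed = 1L) {
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  s <- max(3L, round(supportFraction * p))
  Tm <- matrix(0, p, k)
  for (a in seq_len(k)) {
    idx <- sample(p, s)
    Tm[idx, a] <- runif(s)
  }
  Tm <- normalizeColumns(Tm)
  dimnames(Tm) <- list(paste0("feature", seq_len(p)),
                       paste0("type", seq_len(k)))
  Tm
}

#' Correlated per-class type matrices from a shared pool
#'
#' Emulates type matrices estimated from the two classes of a single
#' cohort: a pool of `max(kByClass)` correlated types is built from one
#' sparse base composition with per-type lognormal tilts (`sigma`), and
#' each class receives the first `kByClass[c]` pool types, each with a
#' smaller class-specific lognormal perturbation (`delta`). Classes thus
#' share most of their subcommunity structure and differ both in the
#' extra types and in small compositional shifts of the shared ones --
#' the regime in which underfitted models leave the two classes' deviance
#' distributions overlapping.
#'
#' @param p number of features.
#' @param kByClass integer vector of types per class.
#' @param sigma log-scale spread between pool types (within-class
#'   diversity).
#' @param delta log-scale class-specific perturbation of shared types
#'   (between-class divergence); should be below `sigma`.
#' @param supportFraction fraction of features in the base support.
#' @param seed integer seed.
#' @return list of type matrices, one per class, unit column sums.
#' @export
classTypePool <- function(p, kByClass, sigma = 1, delta = 0.2,
                          supportFraction = 0.5, seed = 1L) {
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  s <- round(supportFraction * p)
  base <- numeric(p)
  base[sample(p, s)] <- rgamma(s, 0.8)
  kPool <- max(kByClass)
  pool <- vapply(seq_len(kPool), function(a) {
    v <- base * exp(sigma * rnorm(p)); v / sum(v)
  }, numeric(p))
  lapply(kByClass, function(kc) {
    Tm <- vapply(seq_len(kc), function(i) {
      v <- pool[, i] * exp(delta * rnorm(p)); v / sum(v)
    }, numeric(p))
    dimnames(Tm) <- list(paste0("feature", seq_len(p)),
                         paste0("type", seq_len(kc)))
    Tm
  })
}
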