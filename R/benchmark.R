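## The generative benchmark pipeline: simulate counts from known
## per-class types, choose the number of types per class on the training
## half by the cross-validated Wilcoxon procedure, fit the supervised
## model with the chosen numbers, and report the test error.

#' Run one replicate of the generative benchmark
#'
#' Simulates `nPerClass` samples per class from the given true type
#' matrices (uniform or zero-inflated Dirichlet weights, optional
#' Gaussian perturbation of the Poisson mean), splits each class in half
#' into training and test sets, selects the number of types per class on
#' the training data with [selectNumTypes()], fits [fitSupervisedNMF()]
#' with the chosen numbers, and classifies the test samples.
#'
#' @param typesByClass list of true type matrices, one per class (e.g.
#'   from [classTypePool()]).
#' @param nPerClass samples per class (half train, half test).
#' @param depth sequencing depth per sample.
#' @param snr signal-to-noise ratio for [noiseSd()] (default `Inf`, no
#'   perturbation); the SD vector is computed from each class's true
#'   types.
#' @param zeroInflated draw weights from Dirichlet(`alpha`) instead of
#'   uniform.
#' @param alpha Dirichlet concentration for the zero-inflated generator.
#' @param kGrid candidate numbers of types.
#' @param r folds for the selection procedure.
#' @param seed integer seed.
#' @return list with `testError`, `chosenK` (per class), `model`, and the
#'   simulated `train`/`test` data (counts and labels).
#' @export
runGenerativeBenchmark <- function(typesByClass, nPerClass = 200L,
                                   depth = 1e4, snr = Inf,
                                   zeroInflated = FALSE, alpha = 0.005,
                                   kGrid = 1:5, r = 10L, seed = 1L) {
  g <- length(typesByClass)
  seeds <- .subSeeds(seed, 2 * g + 1)
  sim <- function(Tm, s) {
    sdv <- noiseSd(Tm, snr)
    if (zeroInflated)
      simulateZeroInflated(Tm, rep(depth, nPerClass), alpha = alpha,
                           sdVector = sdv, seed = s)$counts
    else
      simulateFromTypes(Tm, rep(depth, nPerClass), sdVector = sdv,
                        seed = s)$counts
  }
  Xc <- lapply(seq_len(g), function(c) sim(typesByClass[[c]], seeds[c]))
  nTrain <- nPerClass %/% 2
  trainX <- lapply(Xc, function(X) X[, seq_len(nTrain), drop = FALSE])
  testX <- lapply(Xc, function(X) X[, -seq_len(nTrain), drop = FALSE])

  chosen <- vapply(seq_len(g), function(c) {
    sel <- selectNumTypes(trainX[[c]], trainX[-c], kGrid = kGrid, r = r,
                          seed = seeds[g + c])
    chosenK(sel)
  }, integer(1))
  cls <- paste0("class", seq_len(g))
  names(chosen) <- cls

  trainAll <- do.call(cbind, trainX)
  colnames(trainAll) <- paste0("train", seq_len(ncol(trainAll)))
  trainLab <- factor(rep(cls, each = nTrain), levels = cls)
  testAll <- do.call(cbind, testX)
  colnames(testAll) <- paste0("test", seq_len(ncol(testAll)))
  testLab <- factor(rep(cls, vapply(testX, ncol, integer(1))),
                    levels = cls)

  model <- fitSupervisedNMF(trainAll, trainLab, kByClass = chosen,
                            seed = seeds[2 * g + 1])
  pred <- predict(model, testAll)
  err <- mean(as.character(pred$labels) != as.character(testLab))
  list(testError = err, chosenK = chosen, model = model,
       train = list(counts = trainAll, labels = trainLab),
       test = list(counts = testAll, labels = testLab,
                   predicted = pred$labels))
}

#' Subcommunity recovery on one Holling type II dataset
#'
#' Simulates one dataset from a Holling system, extracts candidate
#' clusters both from an NMF fit (abundance-threshold sweep per type) and
#' from a permutation co-occurrence network (connected components across
#' significance levels), and scores each true subcommunity with the
#' minimum recovery loss over unions of candidates.
#'
#' @param system a [HollingSystem-class].
#' @param nSamples samples to simulate.
#' @param nTypes NMF types to fit (default 4).
#' @param nSteps Euler steps per sample.
#' @param nPerm permutations for the co-occurrence network.
#' @param seed integer seed.
#' @return data.frame with one row per true cluster and columns
#'   `nmfLoss`, `coocLoss`.
#' @export
hollingRecovery <- function(system, nSamples = 200L, nTypes = 4L,
                            nSteps = 1e5, nPerm = 1000L, seed = 1L) {
  seeds <- .subSeeds(seed, 3)
  sim <- simulateHolling(system, nSamples, seed = seeds[1],
                         nSteps = nSteps)
  X <- sim$counts
  keep <- colSums(X) > 0   # samples where every OTU died out carry nothing
  X <- X[, keep, drop = FALSE]
  fit <- fitNMF(X, nTypes, seed = seeds[2])
  famNMF <- nmfClusterFamily(fit)
  net <- cooccurrenceNetwork(sim$abundances[, keep, drop = FALSE],
                             nPerm = nPerm, seed = seeds[3])
  famCooc <- cooccurrenceClusterFamily(net)
  res <- data.frame(
    cluster = vapply(system@clusters, function(cl)
      paste0("M", min(cl), "-M", max(cl)), character(1)),
    nmfLoss = vapply(system@clusters, function(cl)
      optimalLoss(cl, famNMF)$loss, integer(1)),
    coocLoss = vapply(system@clusters, function(cl)
      optimalLoss(cl, famCooc)$loss, integer(1)))
  res
}
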