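## Supervised NMF: fit a type matrix per class, concatenate, project all
## samples onto the combined types by non-negative Poisson regression,
## normalize the weights to unit column sums, and train a logistic
## classifier on the transposed normalized weights. Per-class observation
## weights (used e.g. to balance unequal class sizes) enter only the
## classifier, never the fitted T or W.

## glmnet with an effectively-zero ridge penalty: plain logistic
## regression with a numerical guard for separable training sets.
.fitLogistic <- function(Wn, labels, obsWeights) {
  x <- t(Wn)
  if (nlevels(labels) == 2) {
    glmnet::glmnet(x, labels, family = "binomial", alpha = 0,
                   lambda = 1e-8, weights = obsWeights,
                   standardize = FALSE)
  } else {
    ## one-vs-rest
    lapply(levels(labels), function(cl)
      glmnet::glmnet(x, factor(labels == cl, c(FALSE, TRUE)),
                     family = "binomial", alpha = 0, lambda = 1e-8,
                     weights = obsWeights, standardize = FALSE))
  }
}

.predictLogistic <- function(classifier, classLevels, Wn) {
  x <- t(Wn)
  if (length(classLevels) == 2) {
    pr <- predict(classifier, newx = x, type = "response")[, 1]
    factor(classLevels[1 + (pr > 0.5)], levels = classLevels)
  } else {
    scores <- vapply(classifier, function(f)
      predict(f, newx = x, type = "link")[, 1], numeric(nrow(x)))
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
    factor(classLevels[max.col(scores, ties.method = "first")],
           levels = classLevels)
  }
}

.expandClassWeights <- function(labels, classWeights) {
  w <- rep(1, length(labels))
  if (!is.null(classWeights)) {
    if (is.null(names(classWeights)))
      stop("classWeights must be named by class")
    for (cl in names(classWeights)) w[labels == cl] <- classWeights[[cl]]
  }
  w
}

#' Fit a supervised NMF classifier
#'
#' Runs [fitNMF()] separately on each class's samples, concatenates the
#' per-class type matrices (columns tagged by class), computes the raw
#' training weights by non-negative Poisson regression of every sample on
#' the combined types, normalizes the weight columns to sum 1, and trains
#' a logistic classifier on the transposed normalized weights.
#'
#' @param X count matrix (features x samples).
#' @param labels class label per sample (factor or character); at least
#'   two classes, each non-empty.
#' @param kByClass named integer vector: number of types per class. Each
#'   class must have at least as many samples as types.
#' @param seed integer seed (per-class NMF seeds are derived from it).
#' @param classWeights optional named per-class observation weights for
#'   the classifier (they do not affect the fitted T or W).
#' @param epsilon re-entry weight of the Poisson regression.
#' @param ... passed to [fitNMF()].
#' @return a [SupervisedNMF-class] model.
#' @export
#' @examples
#' Tm <- cbind(c(.9, .1, 0, 0), c(0, 0, .1, .9))
#' rownames(Tm) <- paste0("f", 1:4)
#' X <- cbind(matrix(rpois(40, Tm[, 1] * 500), 4),
#'            matrix(rpois(40, Tm[, 2] * 500), 4))
#' rownames(X) <- rownames(Tm)
#' fit <- fitSupervisedNMF(X, rep(c("a", "b"), each = 10),
#'                         kByClass = c(a = 1, b = 1), seed = 1)
fitSupervisedNMF <- function(X, labels, kByClass, seed,
                             classWeights = NULL, epsilon = 1e-7, ...) {
  X <- asCountMatrix(X, requireIntegers = FALSE)
  labels <- checkPartition(labels, ncol(X))
  if (nlevels(labels) < 2)
    stop("supervised NMF needs at least two classes")
  cls <- levels(labels)
  if (is.null(names(kByClass)) || !setequal(names(kByClass), cls))
    stop("kByClass must be named with exactly the class labels")
  kByClass <- vapply(cls, function(cl) as.integer(kByClass[[cl]]),
                     integer(1))
  seeds <- .subSeeds(seed, length(cls))

  typesList <- vector("list", length(cls))
  for (i in seq_along(cls)) {
    idx <- which(labels == cls[i])
    if (length(idx) < kByClass[i])
      stop(sprintf("class '%s' has %d samples but %d types requested",
                   cls[i], length(idx), kByClass[i]))
    fit <- fitNMF(X[, idx, drop = FALSE], kByClass[i], seed = seeds[i], ...)
    typesList[[i]] <- typeMatrix(fit)
  }
  Tcomb <- do.call(cbind, typesList)
  typeClass <- factor(rep(cls, kByClass), levels = cls)
  colnames(Tcomb) <- paste0(typeClass, ".type",
                            unlist(lapply(kByClass, seq_len)))

  tr <- transformSamples(Tcomb, X, epsilon = epsilon)
  Wn <- normalizeColumns(tr$weights)
  obsW <- .expandClassWeights(labels, classWeights)
  classifier <- .fitLogistic(Wn, labels, obsW)

  new("SupervisedNMF", types = Tcomb, typeClass = typeClass,
      kByClass = kByClass, classifier = classifier, classLevels = cls,
      classWeights = if (is.null(classWeights)) numeric(0)
                     else unlist(classWeights),
      trainWeights = Wn, trainLabels = labels,
      epsilon = epsilon, seed = as.integer(seed))
}

#' Predict class labels for new samples
#'
#' New samples are projected onto the frozen combined type matrix by
#' non-negative Poisson regression, the weights normalized to unit column
#' sum (removing sequencing depth), and the trained logistic classifier
#' applied.
#'
#' @param object a [SupervisedNMF-class] model.
#' @param newdata count matrix of new samples (features aligned by ID).
#' @param ... ignored.
#' @return list with `labels` (factor) and `weights` (normalized k x n
#'   weight matrix, for inspection and plotting).
#' @export
setMethod("predict", "SupervisedNMF", function(object, newdata, ...) {
  tr <- transformSamples(object@types, newdata, epsilon = object@epsilon)
  Wn <- normalizeColumns(tr$weights)
  labels <- .predictLogistic(object@classifier, object@classLevels, Wn)
  names(labels) <- colnames(Wn)
  list(labels = labels, weights = Wn)
})

## Fold assignment: random folds are stratified by class so every
## training set contains every class; sequential folds are contiguous
## blocks in sample order (for time-indexed designs).
.makeFolds <- function(labels, nFolds, scheme, seed) {
  n <- length(labels)
  folds <- integer(n)
  if (scheme == "sequential") {
    folds <- cut(seq_len(n), breaks = nFolds, labels = FALSE)
  } else {
    old <- .saveRNG(); on.exit(.restoreRNG(old))
    set.seed(as.integer(seed))
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep(seq_len(nFolds), length.out = length(idx)))
    }
  }
  folds
}

#' Cross-validated error of supervised NMF
#'
#' For each fold, per-class types are refitted on the training folds
#' only, the held-out fold is classified, and the (optionally
#' class-weighted) misclassification fraction recorded.
#'
#' @param X count matrix.
#' @param labels class labels.
#' @param kByClass named types-per-class vector.
#' @param nFolds number of folds (>= 2).
#' @param seed integer seed.
#' @param foldScheme `"random"` (stratified by class) or `"sequential"`
#'   (contiguous blocks in sample order, for time series).
#' @param classWeights optional named per-class weights; when given, fold
#'   errors are weighted misclassification fractions.
#' @param ... passed to [fitSupervisedNMF()].
#' @return list with `foldErrors`, `mean`, `se` (standard error of the
#'   mean over folds), and `folds` (the fold assignment).
#' @export
crossValidate <- function(X, labels, kByClass, nFolds = 10L, seed = 1L,
                          foldScheme = c("random", "sequential"),
                          classWeights = NULL, ...) {
  foldScheme <- match.arg(foldScheme)
  X <- asCountMatrix(X, requireIntegers = FALSE)
  labels <- checkPartition(labels, ncol(X))
  if (nFolds < 2) stop("nFolds must be at least 2")
  folds <- .makeFolds(labels, nFolds, foldScheme, seed)
  seeds <- .subSeeds(seed, nFolds)

  errs <- rep(NA_real_, nFolds)
  for (f in seq_len(nFolds)) {
    trainIdx <- which(folds != f)
    testIdx <- which(folds == f)
    trainLab <- droplevels(labels[trainIdx])
    if (nlevels(trainLab) < nlevels(labels)) {
      warning(sprintf("fold %d: a class is missing from training; skipped", f))
      next
    }
    model <- fitSupervisedNMF(X[, trainIdx, drop = FALSE], trainLab,
                              kByClass = kByClass, seed = seeds[f],
                              classWeights = classWeights, ...)
    pred <- predict(model, X[, testIdx, drop = FALSE])$labels
    truth <- labels[testIdx]
    w <- .expandClassWeights(truth, classWeights)
    errs[f] <- sum(w * (as.character(pred) != as.character(truth))) / sum(w)
  }
  ok <- !is.na(errs)
  list(foldErrors = errs,
       mean = mean(errs[ok]),
       se = if (sum(ok) > 1) sd(errs[ok]) / sqrt(sum(ok)) else NA_real_,
       folds = folds)
}
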