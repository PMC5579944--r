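#' Fitted Poisson NMF model
#'
#' Result of [fitNMF()]. The type matrix has one column per subcommunity
#' ("type"); each column is a composition over features and sums to 1.
#' The raw weight matrix absorbs sequencing depth: its column sums equal
#' the column sums of the count matrix that was factorized.
#'
#' @slot types p x k non-negative matrix, columns sum to 1.
#' @slot weights k x n non-negative matrix on the raw (depth) scale.
#' @slot loglik final Poisson log-likelihood.
#' @slot loglikTrace log-likelihood after each update sweep.
#' @slot nIter number of update sweeps performed.
#' @slot converged logical, relative-improvement tolerance reached.
#' @slot seed integer seed used for the random initialization.
#'
#' @aliases PoissonNMF
#' @exportClass PoissonNMF
setClass("PoissonNMF",
  representation(
    types = "matrix",
    weights = "matrix",
    loglik = "numeric",
    loglikTrace = "numeric",
    nIter = "integer",
    converged = "logical",
    seed = "integer"
  )
)

setValidity("PoissonNMF", function(object) {
  msg <- character()
  Tm <- object@types
  Wm <- object@weights
  if (any(Tm < 0)) msg <- c(msg, "type matrix has negative entries")
  if (any(Wm < 0)) msg <- c(msg, "weight matrix has negative entries")
  if (ncol(Tm) != nrow(Wm))
    msg <- c(msg, "ncol(types) must equal nrow(weights)")
  if (ncol(Tm) > 0 && any(abs(colSums(Tm) - 1) > 1e-8))
    msg <- c(msg, "type columns must sum to 1 (tolerance 1e-8)")
  if (length(msg)) msg else TRUE
})

#' Supervised NMF model
#'
#' Result of [fitSupervisedNMF()]: per-class type matrices concatenated
#' into one combined type matrix (columns tagged by class of origin), the
#' normalized training weights, and a logistic classifier (ridge penalty
#' 1e-8, a numerical guard only) trained on the transposed normalized
#' weight matrix.
#'
#' @slot types p x k combined type matrix, unit column sums.
#' @slot typeClass factor of length k tagging each type column with the
#'   class it was fitted on.
#' @slot kByClass named integer vector, number of types per class.
#' @slot classifier fitted `glmnet` object (binomial or one-vs-rest list).
#' @slot classLevels character vector of class labels.
#' @slot classWeights named per-class observation weights used by the
#'   classifier (they never affect the fitted T or W).
#' @slot trainWeights k x n normalized training weight matrix.
#' @slot trainLabels factor of training labels.
#' @slot epsilon re-entry step used by the non-negative Poisson regression.
#' @slot seed integer seed.
#'
#' @aliases SupervisedNMF
#' @exportClass SupervisedNMF
setClass("SupervisedNMF",
  representation(
    types = "matrix",
    typeClass = "factor",
    kByClass = "integer",
    classifier = "ANY",
    classLevels = "character",
    classWeights = "numeric",
    trainWeights = "matrix",
    trainLabels = "factor",
    epsilon = "numeric",
    seed = "integer"
  )
)

setValidity("SupervisedNMF", function(object) {
  msg <- character()
  if (length(object@typeClass) != ncol(object@types))
    msg <- c(msg, "typeClass must tag every type column")
  if (ncol(object@types) > 0 && any(abs(colSums(object@types) - 1) > 1e-8))
    msg <- c(msg, "type columns must sum to 1")
  if (!all(levels(object@typeClass) %in% object@classLevels))
    msg <- c(msg, "typeClass levels must be drawn from classLevels")
  if (length(msg)) msg else TRUE
})

#' Report from the type-number selection procedure
#'
#' Result of [selectNumTypes()]. For each candidate number of types k the
#' procedure records one Wilcoxon rank-sum Z value per cross-validation
#' fold (positive Z: the other class's deviances are larger, i.e. the
#' fitted types describe their own class better), the combined statistic
#' \eqn{Z_{all} = \sum_f Z_f / \sqrt{r}}, and the sample standard
#' deviation of the fold Z values. The chosen k is the smallest candidate
#' whose \eqn{Z_{all}} is within one such standard deviation of the
#' maximum.
#'
#' @slot kGrid candidate numbers of types.
#' @slot zByFold r x length(kGrid) matrix of per-fold Z values (NA where a
#'   fit was infeasible).
#' @slot zAll combined statistic per k.
#' @slot sdZAll sample SD of the fold Z values per k.
#' @slot chosenK selected number of types.
#' @slot folds number of cross-validation folds r.
#'
#' @aliases TypeSelection
#' @exportClass TypeSelection
setClass("TypeSelection",
  representation(
    kGrid = "integer",
    zByFold = "matrix",
    zAll = "numeric",
    sdZAll = "numeric",
    chosenK = "integer",
    folds = "integer"
  )
)

setValidity("TypeSelection", function(object) {
  msg <- character()
  nk <- length(object@kGrid)
  if (length(object@zAll) != nk || length(object@sdZAll) != nk)
    msg <- c(msg, "zAll and sdZAll must align with kGrid")
  if (ncol(object@zByFold) != nk)
    msg <- c(msg, "zByFold must have one column per candidate k")
  if (!(object@chosenK %in% object@kGrid))
    msg <- c(msg, "chosenK must be an element of kGrid")
  if (length(msg)) msg else TRUE
})

#' Holling type II interaction system
#'
#' A fixed interaction network with drawn parameters for the community
#' dynamics model
#' \deqn{dM_i/dt = M_i ( r_i (1 - c_i M_i) +
#'   \sum_{j \ne i} b_{ij} a_{ij} M_j / (1 + a_{ij} T_{H,ij} M_j) )}
#' Interaction coefficients, attack rates and handling times are fixed per
#' system; the per-sample growth rates \eqn{r_i} and intraspecific
#' coefficients \eqn{c_i} are drawn at simulation time.
#'
#' @slot nOtus number of OTUs (nodes).
#' @slot edges data.frame with columns `from`, `to`, `color` (black, blue
#'   or red), `b`, `a`, `th`; each row is a directed influence of `from`
#'   on the growth of `to`.
#' @slot clusters list of integer vectors: ground-truth subcommunities.
#' @slot seed integer seed used to draw the edge parameters.
#'
#' @aliases HollingSystem
#' @exportClass HollingSystem
setClass("HollingSystem",
  representation(
    nOtus = "integer",
    edges = "data.frame",
    clusters = "list",
    seed = "integer"
  )
)

setValidity("HollingSystem", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("from", "to", "color", "b", "a", "th")
  if (!all(need %in% names(e)))
    msg <- c(msg, "edges must have columns from, to, color, b, a, th")
  else {
    if (nrow(e) && (any(e$from < 1) || any(e$to > object@nOtus)))
      msg <- c(msg, "edge endpoints out of range")
    if (nrow(e) && any(e$from == e$to))
      msg <- c(msg, "self-edges are not allowed (intraspecific term is c_i)")
    ok <- rep(TRUE, nrow(e))
    ok[e$color == "black"] <- e$b[e$color == "black"] >= 0 &
      e$b[e$color == "black"] <= 0.008
    ok[e$color == "blue"] <- e$b[e$color == "blue"] >= -0.002 &
      e$b[e$color == "blue"] <= 0.008
    ok[e$color == "red"] <- e$b[e$color == "red"] >= -0.08 &
      e$b[e$color == "red"] <= 0
    if (nrow(e) && !all(ok))
      msg <- c(msg, "interaction coefficient outside its edge-color range")
    if (nrow(e) && any(e$th <= 0))
      msg <- c(msg, "handling times must be positive")
  }
  if (any(vapply(object@clusters, function(cl)
    any(cl < 1 | cl > object@nOtus), logical(1))))
    msg <- c(msg, "cluster members out of range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PoissonNMF", function(object) {
  cat("PoissonNMF fit\n")
  cat("  features:", nrow(object@types),
      " samples:", ncol(object@weights),
      " types:", ncol(object@types), "\n")
  cat(sprintf("  log-likelihood: %.4f after %d sweeps (%s)\n",
              object@loglik, object@nIter,
              if (object@converged) "converged" else "max iterations"))
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "SupervisedNMF", function(object) {
  cat("SupervisedNMF model\n")
  cat("  classes:", paste(object@classLevels, collapse = ", "), "\n")
  cat("  types per class:",
      paste(sprintf("%s=%d", names(object@kByClass), object@kByClass),
            collapse = ", "), "\n")
  cat("  features:", nrow(object@types),
      " training samples:", ncol(object@trainWeights), "\n")
})

setMethod("show", "TypeSelection", function(object) {
  cat("Type-number selection (", object@folds, "-fold CV)\n", sep = "")
  tab <- data.frame(k = object@kGrid, Zall = round(object@zAll, 3),
                    sd = round(object@sdZAll, 3))
  print(tab, row.names = FALSE)
  cat("  chosen k:", object@chosenK, "\n")
})

setMethod("show", "HollingSystem", function(object) {
  cat("HollingSystem:", object@nOtus, "OTUs,",
      nrow(object@edges), "directed edges,",
      length(object@clusters), "ground-truth subcommunities\n")
})
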