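#' Accessors for fitted models
#'
#' `typeMatrix()` returns the (combined) type matrix, `weightMatrix()` the
#' weight matrix (`normalized = TRUE` rescales columns to sum 1),
#' `chosenK()` the selected number of types of a [TypeSelection-class]
#' report.
#'
#' @param object a fitted object.
#' @param ... passed to methods.
#' @return a matrix (`typeMatrix`, `weightMatrix`) or integer (`chosenK`).
#' @name accessors
#' @examples
#' X <- matrix(rpois(60, 5), nrow = 6)
#' fit <- fitNMF(X, k = 2, seed = 1)
#' dim(typeMatrix(fit))
#' colSums(weightMatrix(fit, normalized = TRUE))
NULL

#' @rdname accessors
#' @export
setGeneric("typeMatrix", function(object, ...) standardGeneric("typeMatrix"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix",
           function(object, ...) standardGeneric("weightMatrix"))

#' @rdname accessors
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))

#' @rdname accessors
#' @export
setMethod("typeMatrix", "PoissonNMF", function(object, ...) object@types)

#' @rdname accessors
#' @export
setMethod("typeMatrix", "SupervisedNMF", function(object, ...) object@types)

#' @rdname accessors
#' @param normalized logical; rescale weight columns to sum 1.
#' @export
setMethod("weightMatrix", "PoissonNMF",
  function(object, normalized = FALSE, ...) {
    W <- object@weights
    if (normalized) W <- normalizeColumns(W)
    W
  })

#' @rdname accessors
#' @export
setMethod("weightMatrix", "SupervisedNMF",
  function(object, ...) object@trainWeights)

#' @rdname accessors
#' @export
setMethod("chosenK", "TypeSelection", function(object) object@chosenK)

#' @rdname accessors
#' @export
setMethod("logLik", "PoissonNMF", function(object, ...) object@loglik)
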