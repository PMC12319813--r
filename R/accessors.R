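#' Accessors for fitted objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a fitted object ([GLMFit-class], [NormativeModel-class],
#'   [SpatialGradientFit-class] or [SignalDictionary-class]).
#' @return `coefficients()` returns the named estimates; `zStatistics()` the
#'   per-regressor z-statistics; `gradientCoefficients()` the named
#'   `c(LM, PA, IS)` gradient vector (units/mm); `kernelHyperparameters()`
#'   the named GP kernel hyperparameters; `r1Grid()`/`b1Grid()` the
#'   dictionary grids.
#' @examples
#' X <- cbind(intercept = 1, age = 20:59, age2 = (20:59)^2,
#'            sex_c = rep(c(-.5, .5), 20), hemi_c = rep(c(-.5, .5), each = 20))
#' fit <- fitGLM(rnorm(40) + 0.05 * (20:59), X)
#' zStatistics(fit)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("zStatistics", function(object) standardGeneric("zStatistics"))

#' @rdname accessors
#' @export
setMethod("zStatistics", "GLMFit", function(object) object@z)

#' @rdname accessors
#' @export
setMethod("coefficients", "GLMFit", function(object) object@beta)

#' @rdname accessors
#' @export
setGeneric("gradientCoefficients",
           function(object) standardGeneric("gradientCoefficients"))

#' @rdname accessors
#' @export
setMethod("gradientCoefficients", "SpatialGradientFit",
          function(object) c(p0 = object@p0, object@gradient))

#' @rdname accessors
#' @export
setGeneric("kernelHyperparameters",
           function(object) standardGeneric("kernelHyperparameters"))

#' @rdname accessors
#' @export
setMethod("kernelHyperparameters", "NormativeModel",
          function(object) object@hyper)

#' @rdname accessors
#' @export
setGeneric("r1Grid", function(object) standardGeneric("r1Grid"))

#' @rdname accessors
#' @export
setMethod("r1Grid", "SignalDictionary", function(object) object@r1Grid)

#' @rdname accessors
#' @export
setGeneric("b1Grid", function(object) standardGeneric("b1Grid"))

#' @rdname accessors
#' @export
setMethod("b1Grid", "SignalDictionary", function(object) object@b1Grid)
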